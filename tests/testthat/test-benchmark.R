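toyLabels <- function() {
    data.frame(
        id = sprintf("p%02d", 1:18),
        family = rep(c("A1", "A2", "B1", "B2", "C1", "C2"), each = 3),
        superfamily = rep(c("A", "A", "B", "B", "C", "C"), each = 3),
        stringsAsFactors = FALSE)
}

test_that("makeSplit follows the family-holdout membership rules", {
    labels <- toyLabels()
    sp <- makeSplit(labels, "A1")
    expect_identical(sp@posTest, sprintf("p%02d", 1:3))     # family A1
    expect_identical(sp@posTrain, sprintf("p%02d", 4:6))    # rest of A
    ## lexicographic chooser holds out B1 and C1
    expect_identical(sp@negTest, sprintf("p%02d", c(7:9, 13:15)))
    expect_identical(sp@negTrain, sprintf("p%02d", c(10:12, 16:18)))
    expect_identical(sp@extendedPos, character())
    expect_error(makeSplit(labels, "nope"), "unknown family")
})

test_that("a single-family superfamily yields an empty positive train set", {
    labels <- toyLabels()
    labels <- labels[labels$family != "A2", ]
    expect_warning(sp <- makeSplit(labels, "A1"), "no other family")
    expect_identical(sp@posTrain, character())
    expect_identical(sp@posTest, sprintf("p%02d", 1:3))
})

test_that("extended positives join training but never collide", {
    labels <- toyLabels()
    sp <- makeSplit(labels, "A1", extendedPos = c("x1", "x2"))
    expect_identical(sp@extendedPos, c("x1", "x2"))
    expect_error(makeSplit(labels, "A1", extendedPos = "p01"), "collide")
})

test_that("splits partition correctly on random hierarchies", {
    set.seed(19)
    for (rep in 1:50) {
        labels <- randomHierarchyLabels()
        fam <- sample(unique(labels$family), 1L)
        sp <- suppressWarnings(makeSplit(labels, fam))
        sets <- splitSets(sp)[c("posTest", "posTrain", "negTest", "negTrain")]
        all_ids <- unlist(sets)
        ## pairwise disjoint and drawn from the benchmark ids
        expect_identical(anyDuplicated(all_ids), 0L)
        expect_true(all(all_ids %in% labels$id))
        sf <- labels$superfamily[match(fam, labels$family)]
        ## positives: exactly the target superfamily, split at the family
        expect_setequal(sets$posTest, labels$id[labels$family == fam])
        expect_setequal(sets$posTrain,
                        labels$id[labels$superfamily == sf &
                                  labels$family != fam])
        ## each other superfamily donates one whole family to the test side
        others <- setdiff(unique(labels$superfamily), sf)
        expect_setequal(union(sets$negTest, sets$negTrain),
                        labels$id[labels$superfamily %in% others])
        for (o in others) {
            testFams <- unique(labels$family[labels$id %in% sets$negTest &
                                             labels$superfamily == o])
            expect_length(testFams, 1L)
            expect_setequal(labels$id[labels$family == testFams],
                            intersect(sets$negTest,
                                      labels$id[labels$superfamily == o]))
        }
        ## no test protein's family appears on the training side
        trainFams <- labels$family[labels$id %in%
                                   c(sets$posTrain, sets$negTrain)]
        testFams <- labels$family[labels$id %in%
                                  c(sets$posTest, sets$negTest)]
        expect_length(intersect(trainFams, testFams), 0L)
    }
})

test_that("makeAllSplits enumerates eligible families deterministically", {
    labels <- toyLabels()
    splits <- makeAllSplits(labels)
    expect_length(splits, 6L)
    expect_identical(names(splits), sort(unique(labels$family)))
    ## min-positives filter
    labels2 <- labels
    labels2 <- rbind(labels2,
                     data.frame(id = sprintf("q%02d", 1:14),
                                family = rep(c("A1", "B1"), each = 7),
                                superfamily = rep(c("A", "B"), each = 7)))
    expect_length(makeAllSplits(labels2, minPositives = 10L), 2L)
    expect_identical(names(makeAllSplits(labels2, minPositives = 10L)),
                     c("A1", "B1"))
    ## deterministic, including the seeded random chooser
    a <- makeAllSplits(labels, negChooser = "random", seed = 5L)
    b <- makeAllSplits(labels, negChooser = "random", seed = 5L)
    expect_identical(lapply(a, splitSets), lapply(b, splitSets))
})

test_that("split manifests round-trip through JSON", {
    splits <- makeAllSplits(toyLabels())
    path <- withr::local_tempfile(fileext = ".json")
    writeSplitManifest(splits, path)
    back <- readSplitManifest(path)
    expect_identical(lapply(unname(splits), splitSets),
                     lapply(unname(back), splitSets))
})
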