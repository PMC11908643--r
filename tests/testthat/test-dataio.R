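test_that("genotype CSV loads identically and round-trips bit-exactly", {
  d <- matrix(c(0, 1, 2, 2, 0, 1), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("m1", "m2")))
  path <- withr::local_tempfile(fileext = ".csv")
  writeToyCsv(d, path)
  G <- readGenotypes(path, format = "csv")
  expect_identical(sampleIds(G), c("a", "b", "c"))
  expect_identical(markerIds(G), c("m1", "m2"))
  expect_equal(unname(dosages(G)), unname(d))

  out <- withr::local_tempfile(fileext = ".csv")
  writeGenotypes(G, out)
  G2 <- readGenotypes(out, format = "csv")
  expect_identical(dosages(G2), dosages(G))
})

test_that("missing dosages are mean-imputed without touching observed entries", {
  d <- matrix(c(0, 2, NA, 1, 1, 1), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("m1", "m2")))
  path <- withr::local_tempfile(fileext = ".csv")
  writeToyCsv(d, path)
  G <- readGenotypes(path, format = "csv")
  expect_equal(dosages(G)["c", "m1"], 1.0)  # mean of {0, 2}
  expect_equal(dosages(G)[c("a", "b"), "m1"], c(a = 0, b = 2))
  expect_equal(unname(dosages(G)[, "m2"]), c(1, 1, 1))
  expect_true(monomorphicMarkers(G)[["m2"]])
  expect_false(monomorphicMarkers(G)[["m1"]])
})

test_that("plink .raw dosage files parse, agreeing with a text-splitting oracle", {
  lines <- c(
    "FID IID PAT MAT SEX PHENOTYPE snpA_A snpB_G snpC_T snpD_C",
    "f1 id1 0 0 1 -9 0 1 2 0",
    "f2 id2 0 0 2 -9 1 1 0 2",
    "f3 id3 0 0 1 -9 2 0 1 1",
    "f4 id4 0 0 2 -9 0 2 2 1",
    "f5 id5 0 0 1 -9 1 0 0 0")
  path <- withr::local_tempfile(fileext = ".raw")
  writeLines(lines, path)
  G <- readGenotypes(path, format = "plink_raw")
  expect_equal(dim(dosages(G)), c(5L, 4L))
  expect_identical(sampleIds(G), paste0("id", 1:5))

  # independent oracle: split each line on whitespace, take fields 7..10
  fields <- lapply(strsplit(lines[-1], "\\s+"), function(x) as.numeric(x[7:10]))
  oracle <- do.call(rbind, fields)
  expect_equal(unname(dosages(G)), oracle)
})

test_that("genotype reader rejects non-numeric dosages and bad files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,m1,m2", "a,0,1", "b,oops,2", "c,1,0"), path)
  expect_error(readGenotypes(path, "csv"), "non-numeric")
  expect_error(readGenotypes(path, "csv"), "oops")
  expect_error(readGenotypes("no/such/file.csv", "csv"), "not found")
})

test_that("phenotype reader drops missing rows and reports errors usefully", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ttrait1\ttrait2",
               "a\t1.5\t3",
               "b\tNA\t4",
               "c\t2.5\t5",
               "d\tNA\t6",
               "e\t0.5\t7"), path)
  expect_message(y <- readPhenotypes(path, "trait1"), "dropped 2")
  expect_length(phenoValues(y), 3L)
  expect_identical(sampleIds(y), c("a", "c", "e"))
  expect_equal(y@nDropped, 2L)

  y2 <- readPhenotypes(path, "trait2")
  expect_length(phenoValues(y2), 5L)

  expect_error(readPhenotypes(path, "nope"), "trait1, trait2")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ttrait1", "a\t1.5", "b\thigh"), bad)
  expect_error(readPhenotypes(bad, "trait1"), "non-numeric")
})

test_that("alignment restricts to the shared IDs in genotype order", {
  G <- makeToyGenotypes(n = 5)
  y <- phenotypeVector(c(10, 20, 30), sampleIds = c("ind04", "ind01", "ind03"))
  out <- alignData(G, y)
  expect_identical(sampleIds(out$G), c("ind01", "ind03", "ind04"))
  expect_identical(sampleIds(out$y), sampleIds(out$G))
  expect_equal(unname(phenoValues(out$y)), c(20, 30, 10))
  expect_equal(unname(dosages(out$G)), unname(dosages(G)[c(1, 3, 4), ]))

  # identical ID sets pass through unchanged
  yFull <- phenotypeVector(1:5, sampleIds = sampleIds(G))
  out2 <- alignData(G, yFull)
  expect_identical(dosages(out2$G), dosages(G))

  yDisjoint <- phenotypeVector(1:3, sampleIds = c("x", "y", "z"))
  expect_error(alignData(G, yDisjoint), "shared")
})

test_that("outer splits partition exactly, are deterministic and sized by round()", {
  sp <- outerSplit(10, 0.2, seed = 3)
  expect_length(testIdx(sp), 2L)
  expect_length(trainIdx(sp), 8L)
  expect_setequal(c(trainIdx(sp), testIdx(sp)), 1:10)
  expect_length(intersect(trainIdx(sp), testIdx(sp)), 0L)

  expect_identical(outerSplit(10, 0.2, seed = 3), sp)
  expect_false(identical(testIdx(outerSplit(10, 0.2, seed = 4)), testIdx(sp)))

  for (n in c(11, 37, 100)) for (f in c(0.1, 0.25, 0.5)) {
    s <- outerSplit(n, f, seed = 1)
    expect_length(testIdx(s), round(n * f))
    expect_setequal(c(trainIdx(s), testIdx(s)), seq_len(n))
  }
  expect_error(outerSplit(1, 0.2, seed = 1), "split")
  expect_error(outerSplit(10, 1.2, seed = 1), "testFraction")
})

test_that("outer split test membership is uniform across seeds", {
  n <- 1000L
  counts <- integer(n)
  for (s in 1:2000) {
    idx <- testIdx(outerSplit(n, 0.2, seed = s))
    counts[idx] <- counts[idx] + 1L
  }
  freq <- counts / 2000
  expect_true(all(freq > 0.15 & freq < 0.25))
})
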