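test_that("canonical metadata lists 14 sets summing to 87 parameters", {
  meta <- canonicalDescriptorSets()
  expect_equal(nrow(meta), 14L)
  expect_equal(meta$dimension,
               c(3L, 5L, 10L, 3L, 2L, 8L, 6L, 9L, 5L, 8L, 5L, 3L, 8L, 12L))
  expect_equal(sum(meta$dimension), 87L)
})

test_that("loadDescriptorSet validates residues, numerics and dimensions", {
  path <- writeScaleFixture(k = 3L, name = "3z")
  set <- loadDescriptorSet(path, name = "3z")
  expect_s4_class(set, "DescriptorSet")
  expect_equal(descriptorDim(set), 3L)

  # 19-row table: the absent residue is named
  df <- read.csv(path)
  write.csv(df[df$residue != "W", ], path, row.names = FALSE, quote = FALSE)
  expect_error(loadDescriptorSet(path, "broken"), "missing residue.*W")

  # duplicate residue
  df2 <- df; df2$residue[2] <- "A"
  write.csv(df2, path, row.names = FALSE, quote = FALSE)
  expect_error(loadDescriptorSet(path, "broken"), "duplicate residue 'A'")

  # non-numeric cell names row and column
  df3 <- df; df3$p2[5] <- "oops"
  write.csv(df3, path, row.names = FALSE, quote = FALSE)
  expect_error(loadDescriptorSet(path, "broken"),
               "non-numeric value 'oops' at residue 'F', column 'p2'")

  # dimension mismatch against expectation
  path2 <- writeScaleFixture(k = 4L, name = "x")
  expect_error(loadDescriptorSet(path2, "x", expectedDimension = 12L),
               "expected 12 parameter columns, found 4")

  # non-coded residues are rejected
  df4 <- df; df4$residue[1] <- "X"
  write.csv(df4, path, row.names = FALSE, quote = FALSE)
  expect_error(loadDescriptorSet(path, "broken"), "invalid residue 'X'")
})

test_that("canonical sets enforce their published dimension", {
  path <- writeScaleFixture(k = 12L)
  expect_equal(descriptorDim(loadDescriptorSet(path, "HESH",
                                               expectedDimension = 12L)), 12L)
  path3 <- writeScaleFixture(k = 3L)
  expect_error(loadDescriptorSet(path3, "HESH"), "must have 12 parameters")
})

test_that("descriptor tables round-trip bit-exactly through write/load", {
  set <- getDescriptorSet(smallRegistry(), "S1")
  path <- tempfile(fileext = ".csv")
  writeDescriptorSet(set, path)
  back <- loadDescriptorSet(path, "S1")
  expect_identical(descriptorValues(back), descriptorValues(set))
  # tab-separated variant too
  path2 <- tempfile(fileext = ".tsv")
  writeDescriptorSet(set, path2)
  expect_identical(descriptorValues(loadDescriptorSet(path2, "S1")),
                   descriptorValues(set))
})

test_that("totalDimension equals a brute-force sum over active sets", {
  for (seed in 1:3) {
    dims <- sample(1:12, sample(2:8, 1), replace = TRUE)
    reg <- syntheticScales(dims, seed = seed)
    brute <- sum(vapply(registrySetNames(reg),
                        function(nm) ncol(descriptorValues(getDescriptorSet(reg, nm))),
                        integer(1)))
    expect_equal(totalDimension(reg), brute)
    expect_equal(totalDimension(reg), sum(dims))
  }
  expect_equal(totalDimension(canonicalSyntheticRegistry()), 87L)
  expect_equal(totalDimension(syntheticScales(3, seed = 1)), 3L)
  expect_equal(totalDimension(syntheticScales(c(3, 2), seed = 1)), 5L)
})

test_that("synthetic registries are deterministic for a seed", {
  a <- syntheticScales(c(3, 2), seed = 99)
  b <- syntheticScales(c(3, 2), seed = 99)
  c <- syntheticScales(c(3, 2), seed = 100)
  expect_identical(descriptorValues(getDescriptorSet(a, "S1")),
                   descriptorValues(getDescriptorSet(b, "S1")))
  expect_false(identical(descriptorValues(getDescriptorSet(a, "S1")),
                         descriptorValues(getDescriptorSet(c, "S1"))))
})

test_that("set-name aliases resolve to one canonical label", {
  expect_equal(resolveSetName("MS-WHIM-extended"), "MS-WHIM")
  expect_equal(resolveSetName("VHSE"), "VHSE")
  reg <- canonicalSyntheticRegistry()
  expect_identical(getDescriptorSet(reg, "MS-WHIM-extended"),
                   getDescriptorSet(reg, "MS-WHIM"))
})

test_that("registry manifests round-trip a registry", {
  reg <- syntheticScales(c(3, 2, 5), seed = 4)
  dir <- tempfile()
  manifest <- writeRegistryManifest(reg, dir)
  back <- readRegistryManifest(manifest)
  expect_equal(registrySetNames(back), registrySetNames(reg))
  expect_identical(descriptorValues(getDescriptorSet(back, "S3")),
                   descriptorValues(getDescriptorSet(reg, "S3")))
})

test_that("empty or malformed registries are rejected", {
  expect_error(ScaleRegistry(list()), "at least one")
  s <- getDescriptorSet(smallRegistry(), "S1")
  expect_error(ScaleRegistry(s, s), "duplicate set name")
})
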