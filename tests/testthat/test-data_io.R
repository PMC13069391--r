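test_that("a minimal well-formed file loads with the right shape", {
  path <- write_fixture_csv(data.frame(OTU = c("A", "A"), SVL = c(10, 20),
                                       HL = c(2, 3)))
  ds <- read_morphometrics(path)
  expect_s3_class(ds, "morpho_dataset")
  expect_equal(dim(ds), c(2, 1))
  expect_equal(ds$otu, c("A", "A"))
  expect_equal(unname(ds$characters[, "HL"]), c(2, 3))
})

test_that("validation errors identify the offending cell", {
  blank <- write_fixture_csv(data.frame(OTU = c("A", "A"), SVL = c(10, ""),
                                        HL = c(2, 3)))
  expect_error(read_morphometrics(blank), "row 2.*SVL")
  text <- write_fixture_csv(data.frame(OTU = c("A", "A"), SVL = c(10, 20),
                                       HL = c("x", "3")))
  expect_error(read_morphometrics(text), "non-numeric.*row 1.*HL")
  nonpos <- write_fixture_csv(data.frame(OTU = c("A", "A"), SVL = c(10, 20),
                                         HL = c(2, -1)))
  expect_error(read_morphometrics(nonpos), "row 2.*HL.*log10")
  dup <- write_fixture_csv(data.frame(specimen = c("s1", "s1"),
                                      OTU = c("A", "A"), SVL = c(10, 20),
                                      HL = c(2, 3)))
  expect_error(read_morphometrics(dup), "duplicate specimen id")
})

test_that("singleton OTUs warn on load and can be dropped", {
  df <- data.frame(OTU = c("A", "A", "B"), SVL = c(10, 20, 30),
                   HL = c(2, 3, 4))
  path <- write_fixture_csv(df)
  expect_warning(ds <- read_morphometrics(path), "singleton.*B")
  expect_equal(dim(ds)[1], 3)
  expect_message(ds2 <- read_morphometrics(path, drop_singletons = TRUE),
                 "dropped singleton")
  expect_equal(ds2$otu, c("A", "A"))
})

test_that("write/read round-trips values at full precision", {
  ds <- tiny_dataset()
  ds$characters[1, 1] <- 2 + 1 / 3
  ds$body_size[2] <- pi * 10
  path <- tempfile(fileext = ".csv")
  write_morphometrics(ds, path)
  back <- read_morphometrics(path)
  expect_equal(back$characters, ds$characters)
  expect_equal(back$body_size, ds$body_size)
  expect_equal(back$otu, ds$otu)
})

test_that("summary statistics match hand arithmetic and degenerate cases", {
  ds <- morpho_dataset(otu = c("A", "A", "B", "B", "B", "C"),
                       body_size = c(10, 10, 5, 5, 5, 7),
                       characters = cbind(HL = c(2, 3, 5, 5, 5, 4)),
                       warn_singletons = FALSE)
  s <- morpho_summary(ds)
  a <- s[s$otu == "A" & s$character == "HL", ]
  expect_equal(a$n, 2)
  expect_equal(a$mean, 2.5)
  expect_equal(a$sd, sqrt(0.5), tolerance = 1e-12)
  expect_equal(c(a$min, a$max), c(2, 3))
  b <- s[s$otu == "B" & s$character == "HL", ]
  expect_equal(c(b$sd, b$min, b$mean, b$max), c(0, 5, 5, 5))
  cc <- s[s$otu == "C" & s$character == "HL", ]
  expect_equal(cc$n, 1)
  expect_true(is.na(cc$sd))
})

test_that("summary is invariant to specimen order", {
  ds <- tiny_dataset()
  perm <- c(4, 1, 6, 2, 5, 3)
  ds2 <- morpho_dataset(ds$otu[perm], ds$body_size[perm],
                        ds$characters[perm, ], warn_singletons = FALSE)
  expect_equal(morpho_summary(ds2), morpho_summary(ds))
})

test_that("robust outlier screen flags gross values and honors thresholds", {
  ds <- morpho_dataset(otu = rep("A", 5), body_size = rep(10, 5),
                       characters = cbind(HL = c(10, 10, 10, 10, 100)),
                       warn_singletons = FALSE)
  suppressWarnings(out <- flag_outliers(ds, threshold = 3.5,
                                        include_body_size = FALSE))
  expect_equal(nrow(out), 1)
  expect_equal(out$value, 100)
  expect_equal(out$specimen_id, "s005")
  # all-identical character: zero spread, skipped with a warning
  ds2 <- morpho_dataset(otu = rep("A", 4), body_size = 1:4 + 10,
                        characters = cbind(HL = rep(5, 4)),
                        warn_singletons = FALSE)
  expect_warning(out2 <- flag_outliers(ds2, include_body_size = FALSE),
                 "zero spread")
  expect_equal(nrow(out2), 0)
  expect_equal(nrow(suppressWarnings(flag_outliers(ds, threshold = Inf))), 0)
})

test_that("lowering the threshold can only add flagged entries", {
  withr::with_seed(11, {
    ds <- morpho_dataset(otu = rep(c("A", "B"), each = 20),
                         body_size = runif(40, 10, 20),
                         characters = cbind(HL = rlnorm(40, 1, 0.4),
                                            HW = rlnorm(40, 0, 0.3)),
                         warn_singletons = FALSE)
  })
  key <- function(df) paste(df$specimen_id, df$character)
  for (th in c(3.5, 2.5, 1.5, 0.5)) {
    lo <- suppressWarnings(flag_outliers(ds, threshold = th))
    hi <- suppressWarnings(flag_outliers(ds, threshold = th + 1))
    expect_true(all(key(hi) %in% key(lo)))
  }
})

test_that("scheme files align, allow lumping and splitting, and catch id errors", {
  ds <- morpho_dataset(otu = c("A", "A", "B", "B", "C", "C"),
                       body_size = rep(10, 6),
                       characters = cbind(HL = 1:6), warn_singletons = FALSE)
  sc <- write_fixture_csv(data.frame(
    specimen = rev(ds$specimen_ids),   # shuffled on purpose
    lump = rev(c("A", "A", "BC", "BC", "BC", "BC")),
    split = rev(c("A1", "A2", "B", "B", "C", "C"))))
  schemes <- read_schemes(sc, ds)
  expect_named(schemes, c("lump", "split"))
  expect_equal(length(unique(schemes$lump)), 2)  # K = 2 for a 3-OTU dataset
  expect_equal(schemes$split[1:2], c("A1", "A2"))  # splits within an OTU allowed
  bad <- write_fixture_csv(data.frame(specimen = ds$specimen_ids[-3],
                                      s1 = rep("X", 5)))
  expect_error(read_schemes(bad, ds), "s003")
})
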