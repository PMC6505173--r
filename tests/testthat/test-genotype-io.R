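# IO, recoding to the founder major allele, informative-marker filtering,
# and founder MAF classes.

test_that("call coding round-trips and unparseable tokens become missing", {
  calls <- matrix(c("AA", "AB", "BB", "AB", "BB", "AA"), 3, 2,
                  dimnames = list(c("m1", "m2", "m3"), c("s1", "s2")))
  g <- calls_to_geno(calls)
  expect_identical(attr(g, "n_unparseable"), 0L)
  expect_false(anyNA(g))
  expect_equal(geno_to_calls(g), calls)
  # missing tokens are silent; garbage warns with a count
  expect_silent(g2 <- calls_to_geno(c("--", "N", "", "NA", "-")))
  expect_true(all(is.na(g2)))
  expect_warning(g3 <- calls_to_geno(c("AA", "XY", "??")), "2 unparseable")
  expect_equal(as.integer(is.na(g3)), c(0L, 1L, 1L))
})

test_that("genotype files read identically under either orientation", {
  d <- withr::local_tempdir()
  calls <- matrix(c("AA", "AB", "BB", "--", "N", "AB"), 3, 2,
                  dimnames = list(paste0("m", 1:3), c("s1", "s2")))
  write.csv(data.frame(marker = rownames(calls), calls),
            file.path(d, "rows.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(id = colnames(calls), t(calls)),
            file.path(d, "cols.csv"), row.names = FALSE, quote = FALSE)
  g1 <- read_genotypes(file.path(d, "rows.csv"))
  g2 <- read_genotypes(file.path(d, "cols.csv"), markers_in_rows = FALSE)
  expect_equal(unclass(g1), unclass(g2), ignore_attr = "n_unparseable")
  expect_equal(sum(is.na(g1)), 2)  # "--" and "N"
  # duplicate ids and markers absent from the map are hard errors
  write.csv(data.frame(marker = c("m1", "m1"), s1 = c("AA", "BB")),
            file.path(d, "dup.csv"), row.names = FALSE)
  expect_error(read_genotypes(file.path(d, "dup.csv")), "duplicate")
  map <- data.frame(marker = c("m1", "m2"), chr = "1", pos = c(0, 1))
  expect_error(read_genotypes(file.path(d, "rows.csv"), map = map), "m3")
})

test_that("recoding picks the founder major allele with alphabetical ties", {
  founders <- rbind(m1 = c("G", "G", "G", "G", "G", "G", "T", "T"),
                    m2 = c("C", "C", "C", "C", "A", "A", "A", "A"),
                    m3 = rep("G", 8),
                    m4 = c("A", "C", "G", "T", "A", "C", "G", "T"),
                    m5 = c("T", "T", "T", "A", "A", "A", "A", "A"))
  raw <- cbind(s1 = c("GT", "CC", "GG", "AC", "TT"),
               s2 = c("TT", "CA", "GG", "AA", "AT"))
  expect_warning(out <- recode_to_founder_major(raw, founders), NA)
  # m1: G major (6 vs 2) -> GT is AB, TT is BB
  expect_equal(unname(out$geno["m1", ]), c(1L, 2L))
  expect_equal(out$info$major[out$info$marker == "m1"], "G")
  # m2: 4-4 tie -> A wins alphabetically, so CC is BB
  expect_equal(out$info$major[out$info$marker == "m2"], "A")
  expect_equal(unname(out$geno["m2", ]), c(2L, 1L))
  # m3: monomorphic, retained but flagged non-informative
  expect_false(out$info$informative[out$info$marker == "m3"])
  # m4: >2 alleles -> dropped and reported
  expect_false("m4" %in% rownames(out$geno))
  expect_equal(out$dropped$reason[out$dropped$marker == "m4"],
               "more_than_two_alleles")
  # m5: A major (5 vs 3) -> founder codes 1 for T carriers
  expect_equal(unname(out$founders["m5", ]), c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
})

test_that("heterozygous founder calls are treated as missing with a warning", {
  founders <- rbind(m1 = c("GT", "G", "G", "G", "T", "T", "T", "T"))
  raw <- cbind(s1 = "GT")
  expect_warning(out <- recode_to_founder_major(raw, founders),
                 "heterozygous founder")
  expect_true(is.na(out$founders["m1", 1]))
  # tie among the 7 informative founders (3 G vs 4 T)? -> T major here
  expect_equal(out$info$major, "T")
})

test_that("informative filter matches brute-force over all founder patterns", {
  # all 3^8 patterns of {A, B, NA}; predicate: both letters observed
  grid <- as.matrix(expand.grid(rep(list(c(0L, 1L, NA)), 8)))
  rownames(grid) <- paste0("p", seq_len(nrow(grid)))
  kept <- filter_informative(grid)
  brute <- apply(grid, 1, function(x) any(x == 0, na.rm = TRUE) &&
                                      any(x == 1, na.rm = TRUE))
  expect_equal(kept, rownames(grid)[brute])
  # spot checks from the contract
  expect_length(filter_informative(rbind(k = c(rep(0L, 7), 1L))), 1)
  expect_length(filter_informative(rbind(k = rep(0L, 8))), 0)
  expect_length(filter_informative(rbind(k = c(rep(0L, 3), rep(NA, 5)))), 0)
})

test_that("founder MAF classes count the minor allele, incomplete wins", {
  f <- rbind(a = c(1L, rep(0L, 7)),
             b = c(rep(1L, 4), rep(0L, 4)),
             c = c(1L, 1L, 0L, 0L, 0L, 0L, 0L, NA),
             d = c(rep(1L, 6), 0L, 0L),  # minor allele is A here
             e = rep(0L, 8))
  cls <- founder_maf_class(f)
  expect_equal(unname(cls), c("1/8", "4/8", "incomplete", "2/8", NA))
})

test_that("MAF class distribution of simulated founders is binomial-conditioned", {
  set.seed(99)
  f <- simulate_founders(4000)
  cls <- founder_maf_class(f)
  obs <- table(cls)[c("1/8", "2/8", "3/8", "4/8")]
  expected <- 4000 * c(16, 56, 112, 70) / 254
  # within ~4 sd of the multinomial expectation
  sds <- sqrt(expected * (1 - c(16, 56, 112, 70) / 254))
  expect_true(all(abs(obs - expected) < 4 * sds))
  expect_length(filter_informative(f), 4000)  # all polymorphic
})

test_that("datasets survive a write/read round trip through the control file", {
  sim <- small_sim(seed = 5, n_x_markers = 20, n_y_markers = 5)
  d <- withr::local_tempdir()
  ctl <- write_dataset(sim$data, d)
  back <- read_control_file(ctl)
  expect_equal(unclass(back$geno), unclass(sim$data$geno),
               ignore_attr = "n_unparseable")
  expect_equal(unclass(back$founders), unclass(sim$data$founders),
               ignore_attr = "n_het_founder")
  expect_equal(back$map, sim$data$map)
  expect_equal(back$covar$sex, sim$data$covar$sex)
  expect_equal(back$int_x, sim$data$int_x, tolerance = 1e-4)
})
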