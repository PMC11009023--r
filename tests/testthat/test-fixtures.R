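test_that("identical seed and config give byte-identical fixture output", {
  cfg <- fixture_config(seed = 5L, n_modalities = 2L,
                        leaves_per_modality = 6L, variable_fraction = 0.5)
  fx1 <- make_fixture(cfg)
  fx2 <- make_fixture(cfg)
  expect_identical(readLines(fx1$spec_path), readLines(fx2$spec_path))
  for (i in seq_along(fx1$onlist_paths)) {
    expect_identical(readLines(fx1$onlist_paths[i]),
                     readLines(fx2$onlist_paths[i]))
  }
  fx3 <- make_fixture(fixture_config(seed = 6L, n_modalities = 2L,
                                     leaves_per_modality = 6L,
                                     variable_fraction = 0.5))
  expect_false(identical(readLines(fx1$spec_path), readLines(fx3$spec_path)))
})

test_that("fixture generation never disturbs the caller's RNG stream", {
  set.seed(99)
  a <- stats::runif(1)
  set.seed(99)
  invisible(make_fixture(fixture_config(seed = 1L)))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("contradictory configs are rejected", {
  expect_error(fixture_config(leaves_per_modality = 1L))
  expect_error(fixture_config(defect = "NOT_A_CODE"), "unknown defect")
  expect_error(fixture_config(n_modalities = 4L))
})

test_that("written fixture files parse back to the in-memory assay", {
  fx <- make_fixture(fixture_config(seed = 8L, variable_fraction = 0.5))
  a <- read_spec(fx$spec_path)
  expect_identical(unclass(a)$library_spec, unclass(fx$assay)$library_spec)
  ## generated onlists read back exactly, plain and gzip
  seqs <- read_onlist(onlist_ref(basename(fx$onlist_paths[1])), fx$dir)
  gz <- file.path(fx$dir, "copy.txt.gz")
  con <- gzfile(gz, "wt"); writeLines(seqs, con); close(con)
  expect_identical(read_onlist(onlist_ref("copy.txt.gz"), fx$dir), seqs)
})

test_that("zero-error simulation recovers barcodes and umi geometry exactly", {
  fx <- make_fixture(fixture_config(seed = 2L, leaves_per_modality = 3L))
  a <- fx$assay
  reads <- simulate_reads(a, "rna", n = 200, seed = 10L, error_rate = 0)
  expect_named(reads, c("rna-R1", "rna-R2"))
  ## barcode occupies the first interval of read 1; extract with index-derived
  ## coordinates computed on the read-1 subtree
  r1 <- find_by_id(a, "rna-R1")
  bc_leaf <- leaves(r1)[[1]]
  expect_identical(bc_leaf$region_type, "barcode")
  onl <- read_onlist(bc_leaf$onlist, fx$dir)
  got <- substr(reads[["rna-R1"]]$sequence, 1, bc_leaf$max_len)
  expect_true(all(got %in% onl))
  ## umi interval from the read-relative layout yields the right lengths
  umi_leaf <- leaves(r1)[[2]]
  umi <- substr(reads[["rna-R1"]]$sequence, bc_leaf$max_len + 1,
                bc_leaf$max_len + umi_leaf$max_len)
  expect_true(all(nchar(umi) == umi_leaf$max_len))
})

test_that("molecule lengths lie within the documented totals", {
  fx <- make_fixture(fixture_config(seed = 4L, leaves_per_modality = 5L,
                                    variable_fraction = 0.6))
  reads <- simulate_reads(fx$assay, "rna", n = 300, seed = 11L)
  total <- nchar(reads[[1]]$sequence) + nchar(reads[[2]]$sequence)
  info <- spec_info(fx$assay)$per_modality
  adapters <- sum(vapply(
    Filter(function(l) l$region_type %in% c("illumina_p5", "illumina_p7"),
           leaves(fx$assay$library_spec[[1]])),
    `[[`, integer(1), "max_len"))
  expect_true(all(total >= info$min_len[1] - adapters))
  expect_true(all(total <= info$max_len[1] - adapters))
})

test_that("substitution errors hit at the binomial rate and never use the same base", {
  fx <- make_fixture(fixture_config(seed = 2L))
  a <- fx$assay
  clean <- simulate_reads(a, "rna", n = 2000, seed = 3L, error_rate = 0)
  noisy <- simulate_reads(a, "rna", n = 2000, seed = 3L, error_rate = 0.05)
  ## same seed: identical molecules before the error layer, so positionwise
  ## differences are exactly the substitutions
  s1 <- strsplit(clean[[2]]$sequence, "")
  s2 <- strsplit(noisy[[2]]$sequence, "")
  expect_identical(lengths(s1), lengths(s2))
  mism <- mapply(function(x, y) sum(x != y), s1, s2)
  n_bases <- sum(lengths(s1))
  p_hat <- sum(mism) / n_bases
  se <- sqrt(0.05 * 0.95 / n_bases)
  expect_lt(abs(p_hat - 0.05), 4 * se)
})

test_that("simulated FASTQ round-trips through write_fastq/read_fastq", {
  fx <- make_fixture(fixture_config(seed = 12L))
  reads <- simulate_reads(fx$assay, "rna", n = 50, seed = 1L)
  path <- file.path(fx$dir, "r1.fastq")
  write_fastq(reads[[1]], path)
  back <- read_fastq(path)
  expect_identical(back, reads[[1]])
  expect_true(all(back$quality == strrep("I", nchar(back$sequence))))
})
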