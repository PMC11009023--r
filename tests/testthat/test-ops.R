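test_that("index on a fixed-geometry spec gives cumulative fixed intervals", {
  iv <- spec_index(toy1(), "rna")$intervals
  expect_identical(iv$region_id, c("barcode", "umi", "cdna"))
  expect_identical(iv$start_min, c(0L, 16L, 28L))
  expect_identical(iv$stop_min, c(16L, 28L, 118L))
  expect_identical(iv$start_min, iv$start_max)
  expect_true(all(iv$fixed))
})

test_that("variable upstream lengths make downstream intervals variable", {
  iv <- spec_index(toy2(), "rna")$intervals
  umi <- iv[iv$region_id == "umi", ]
  expect_identical(umi$start_min, 8L)
  expect_identical(umi$start_max, 12L)
  expect_false(umi$fixed)
  ## brute-force check against every concrete length assignment
  lv <- leaves(toy2()$library_spec[[1]])
  o <- oracle_index(vapply(lv, `[[`, integer(1), "min_len"),
                    vapply(lv, `[[`, integer(1), "max_len"))
  expect_identical(iv$start_min, o$start_min)
  expect_identical(iv$start_max, o$start_max)
  expect_identical(iv$stop_min, o$stop_min)
  expect_identical(iv$stop_max, o$stop_max)
  expect_identical(iv$fixed, o$fixed)
})

test_that("subsetting by region_type filters without shifting coordinates", {
  iv <- spec_index(toy1(), "rna", subset = "umi")$intervals
  expect_identical(nrow(iv), 1L)
  expect_identical(iv$start_min, 16L)
  expect_identical(iv$stop_min, 28L)
  expect_error(spec_index(toy1(), "nope"), "unknown modality")
})

test_that("index matches the exhaustive length-assignment oracle on random trees", {
  for (seed in 1:40) {
    a <- random_tree_assay(seed, max_leaves = 8L, max_range = 2L)
    iv <- spec_index(a, "mod1")$intervals
    lv <- leaves(a$library_spec[[1]])
    o <- oracle_index(vapply(lv, `[[`, integer(1), "min_len"),
                      vapply(lv, `[[`, integer(1), "max_len"))
    expect_identical(iv$start_min, o$start_min, info = paste("seed", seed))
    expect_identical(iv$start_max, o$start_max, info = paste("seed", seed))
    expect_identical(iv$stop_min, o$stop_min, info = paste("seed", seed))
    expect_identical(iv$stop_max, o$stop_max, info = paste("seed", seed))
    expect_identical(iv$fixed, o$fixed, info = paste("seed", seed))
  }
})

test_that("intervals tile the layout contiguously on random fixtures", {
  for (seed in 1:50) {
    fx <- make_fixture(fixture_config(seed = seed,
                                      leaves_per_modality = 2L + seed %% 7L,
                                      variable_fraction = 0.4))
    iv <- spec_index(fx$assay, "rna")$intervals
    n <- nrow(iv)
    expect_identical(iv$start_min[1], 0L)
    expect_identical(iv$start_max[1], 0L)
    if (n > 1) {
      expect_identical(iv$start_min[-1], iv$stop_min[-n])
      expect_identical(iv$start_max[-1], iv$stop_max[-n])
    }
    info <- spec_info(fx$assay)$per_modality
    expect_identical(iv$stop_min[n], info$min_len[info$modality == "rna"])
    expect_identical(iv$stop_max[n], info$max_len[info$modality == "rna"])
  }
})

test_that("format reconstructs blanked meta metadata and is idempotent", {
  a <- toy1()
  blank <- a
  blank$library_spec[[1]]$sequence <- ""
  blank$library_spec[[1]]$min_len <- 0L
  blank$library_spec[[1]]$max_len <- 0L
  restored <- spec_format(blank)
  attr(a, "base_dir") <- NULL
  attr(restored, "base_dir") <- NULL
  expect_identical(restored, a)
  expect_identical(spec_format(restored), restored)

  b <- spec_format(toy2())
  rna <- b$library_spec[[1]]
  ## 8-12 bp barcode + 6 bp umi + 8 bp barcode + 50 bp cdna
  expect_identical(rna$min_len, 72L)
  expect_identical(rna$max_len, 76L)
  o <- oracle_resolve(rna)
  expect_identical(rna$min_len, as.integer(o$min))
  expect_identical(rna$max_len, as.integer(o$max))
})

test_that("modify updates a region, reformats ancestors, keeps value semantics", {
  a <- toy1()
  before_max <- a$library_spec[[1]]$max_len
  b <- spec_modify(a, "barcode", list(max_len = 18L))
  expect_identical(b$library_spec[[1]]$max_len, before_max + 2L)
  ## original untouched
  expect_identical(a$library_spec[[1]]$max_len, before_max)
  ## inverse update restores structural equality
  c2 <- spec_modify(b, "barcode", list(max_len = 16L))
  expect_identical(unclass(c2)$library_spec, unclass(a)$library_spec)
})

test_that("modify rejects invariant-violating updates with the violation code", {
  a <- toy1()
  fx <- find_by_type(a, "rna", "linker")
  adapter <- region("pad", "linker", sequence_type = "fixed",
                    sequence = "ACGT", min_len = 4)
  ## fixed region whose sequence is replaced without updating lengths
  b <- a
  b$library_spec[[1]]$regions <- c(b$library_spec[[1]]$regions, list(adapter))
  b <- spec_format(b)
  expect_error(spec_modify(b, "pad", list(sequence = "ACGTACGT")),
               "FIXED_SEQ_LEN")
  expect_error(spec_modify(a, "umi", list(region_id = "barcode")), "DUP_ID")
  expect_error(spec_modify(a, "ghost", list(max_len = 1L)), "unknown region_id")
  expect_error(spec_modify(a, "umi", list(shoe_size = 9L)), "unknown region field")
})

test_that("split partitions modalities and a merge restores the original", {
  a <- example_assay("shareseq-like")
  parts <- spec_split(a)
  expect_length(parts, 2L)
  expect_identical(vapply(parts, function(p) p$modalities, character(1)),
                   c("rna", "atac"))
  merged <- a
  merged$library_spec <- do.call(c, lapply(parts, function(p) p$library_spec))
  merged$modalities <- vapply(parts, function(p) p$modalities, character(1))
  attr(a, "base_dir") <- NULL
  attr(merged, "base_dir") <- NULL
  expect_identical(merged, a)
  ## leaf count and ids preserved across the split
  all_ids <- unlist(lapply(parts, function(p)
    vapply(leaves(p$library_spec[[1]]), `[[`, character(1), "region_id")))
  orig_ids <- unlist(lapply(a$library_spec, function(t)
    vapply(leaves(t), `[[`, character(1), "region_id")))
  expect_identical(sort(all_ids), sort(orig_ids))

  single <- spec_split(toy1())
  expect_length(single, 1L)
  expect_identical(single[[1]]$library_spec, toy1()$library_spec)
})

test_that("onlist resolution returns single paths verbatim and ordered multifile", {
  expect_identical(onlist_resolve(toy1(), "rna", "barcode"), "barcodes.txt")
  multi <- onlist_resolve(toy2(), "rna", "barcode", combine = "multifile")
  expect_match(multi[1], "barcode1\\.txt$")
  expect_match(multi[2], "barcode2\\.txt$")
  expect_error(onlist_resolve(toy1(), "rna", "gdna"), "no region")
})

test_that("onlist product materializes the row-major Cartesian product", {
  expect_identical(onlist_product(list(c("AA", "CC"), c("G", "T"))),
                   c("AAG", "AAT", "CCG", "CCT"))
  path <- onlist_resolve(toy2(), "rna", "barcode", combine = "product",
                         outdir = withr::local_tempdir())
  lines <- readLines(path)
  l1 <- read_onlist(onlist_ref("barcode1.txt"),
                    dirname(example_spec("indrops-like")))
  l2 <- read_onlist(onlist_ref("barcode2.txt"),
                    dirname(example_spec("indrops-like")))
  expect_length(lines, length(l1) * length(l2))
  ## brute-force double loop oracle
  brute <- character()
  for (x in l1) for (y in l2) brute <- c(brute, paste0(x, y))
  expect_identical(lines, brute)
})

test_that("onlist product cardinality is m*n on random list sizes", {
  set.seed(42)
  for (i in 1:10) {
    m <- sample(1:50, 1); n <- sample(1:50, 1)
    l1 <- sprintf("A%03d", seq_len(m))
    l2 <- sprintf("B%03d", seq_len(n))
    expect_length(onlist_product(list(l1, l2)), m * n)
  }
})

test_that("info summarizes leaves, lengths, and absent descriptions", {
  i1 <- spec_info(toy1())
  expect_identical(i1$per_modality$n_leaves, 3L)
  expect_identical(i1$per_modality$min_len, 118L)
  expect_identical(i1$per_modality$max_len, 118L)
  i2 <- spec_info(toy2())
  expect_identical(i2$per_modality$min_len, 72L)
  expect_identical(i2$per_modality$max_len, 76L)
  nodesc <- toy1()
  nodesc$description <- ""
  expect_null(spec_info(nodesc)$description)
})

test_that("version reports the tool version and echoes the file version", {
  v <- spec_version()
  expect_identical(v$tool_version,
                   as.character(utils::packageVersion("assayspec")))
  expect_null(v$spec_version)
  expect_identical(spec_version(toy1())$spec_version, "0.3.0")
  odd <- toy1()
  odd$seqspec_version <- "banana"
  expect_warning(v2 <- spec_version(odd), "malformed")
  expect_identical(v2$spec_version, "banana")
})
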