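test_that("leaves() returns atomic descendants in 5'-to-3' order", {
  b <- region("B", "barcode", sequence_type = "random", min_len = 4)
  expect_identical(leaves(b)[[1]]$region_id, "B")
  expect_length(leaves(b), 1L)

  u <- region("U", "umi", sequence_type = "random", min_len = 2)
  c1 <- region("C", "cdna", sequence_type = "random", min_len = 9)
  flat <- region("R", sequence_type = "joined", regions = list(b, u, c1))
  expect_identical(vapply(leaves(flat), `[[`, character(1), "region_id"),
                   c("B", "U", "C"))

  a1 <- region("A1", sequence_type = "random", min_len = 1)
  a2 <- region("A2", sequence_type = "random", min_len = 1)
  m <- region("M", sequence_type = "joined", regions = list(a1, a2))
  nested <- region("R2", sequence_type = "joined", regions = list(m, c1))
  got <- vapply(leaves(nested), `[[`, character(1), "region_id")
  want <- vapply(oracle_flatten(nested), `[[`, character(1), "region_id")
  expect_identical(got, c("A1", "A2", "C"))
  expect_identical(got, want)
})

test_that("leaves() agrees with the brute-force flatten oracle on random trees", {
  for (seed in 1:25) {
    a <- random_tree_assay(seed)
    tree <- a$library_spec[[1]]
    expect_identical(
      vapply(leaves(tree), `[[`, character(1), "region_id"),
      vapply(oracle_flatten(tree), `[[`, character(1), "region_id"),
      info = paste("seed", seed))
  }
})

test_that("find_by_id retrieves unique regions and returns NULL on absence", {
  a <- toy1()
  bc <- find_by_id(a, "barcode")
  expect_s3_class(bc, "region")
  expect_identical(bc$region_type, "barcode")
  expect_null(find_by_id(a, "nonexistent"))
  top <- find_by_id(a, "rna")
  expect_identical(top$region_id, "rna")
  expect_gt(length(top$regions), 0L)
})

test_that("find_by_id agrees with an exhaustive traversal oracle", {
  for (seed in 1:20) {
    a <- random_tree_assay(seed)
    ids <- vapply(leaves(a$library_spec[[1]]), `[[`, character(1), "region_id")
    for (id in c(ids, "definitely-not-there")) {
      hits <- oracle_scan_id(a, id)
      got <- find_by_id(a, id)
      if (length(hits) == 0L) expect_null(got)
      else expect_identical(got$region_id, hits[[1]]$region_id)
    }
  }
})

test_that("find_by_type returns matches in pre-order and errors on bad modality", {
  a <- toy1()
  umis <- find_by_type(a, "rna", "umi")
  expect_length(umis, 1L)
  expect_identical(umis[[1]]$region_id, "umi")
  expect_length(find_by_type(a, "rna", "gdna"), 0L)
  expect_error(find_by_type(a, "dna", "umi"), "unknown modality 'dna'")

  b <- toy2()
  bcs <- find_by_type(b, "rna", "barcode")
  expect_identical(vapply(bcs, `[[`, character(1), "region_id"),
                   c("barcode1", "barcode2"))
})

test_that("resolve_joined concatenates children and sums lengths", {
  m <- region("m", sequence_type = "joined", regions = list(
    region("a", "linker", sequence_type = "fixed", sequence = "AC", min_len = 2),
    region("b", "linker", sequence_type = "fixed", sequence = "GT", min_len = 2)
  ))
  r <- resolve_joined(m)
  expect_identical(r$sequence, "ACGT")
  expect_identical(r$min_len, 4L)
  expect_identical(r$max_len, 4L)

  m2 <- region("m2", sequence_type = "joined", regions = list(
    region("a", "linker", sequence_type = "fixed", sequence = "AC", min_len = 2),
    region("b", "custom", sequence_type = "random", min_len = 2, max_len = 3)
  ))
  r2 <- resolve_joined(m2)
  o <- oracle_resolve(m2)
  expect_identical(r2$sequence, "ACXXX")
  expect_identical(r2$min_len, 4L)
  expect_identical(r2$max_len, 5L)
  expect_identical(r2$sequence, o$seq)
  expect_identical(r2$min_len, as.integer(o$min))
})

test_that("resolve_joined is idempotent and errors on childless joined regions", {
  t1 <- toy1()$library_spec[[1]]
  expect_identical(resolve_joined(resolve_joined(t1)), resolve_joined(t1))
  empty <- region("e", sequence_type = "joined")
  expect_error(resolve_joined(empty), "requires children")
})

test_that("length is conserved: leaf sums equal resolved totals; leaves unchanged", {
  for (seed in 1:25) {
    tree <- random_tree_assay(seed)$library_spec[[1]]
    r <- resolve_joined(tree)
    lv <- leaves(tree)
    expect_identical(r$min_len,
                     sum(vapply(lv, `[[`, integer(1), "min_len")))
    expect_identical(r$max_len,
                     sum(vapply(lv, `[[`, integer(1), "max_len")))
    expect_identical(
      vapply(leaves(r), `[[`, character(1), "region_id"),
      vapply(lv, `[[`, character(1), "region_id"))
  }
})
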