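## Canonical Illumina flow-cell adapter sequences used for the fixed
## flanking regions of generated constructs.
P5_SEQ <- "AATGATACGGCGACCACCGAGATCTACAC"
P7_SEQ <- "ATCTCGTATGCCGTCTTCTGCTTG"

DEFECT_CODES <- c("DUP_ID", "LEN_ORDER", "FIXED_SEQ_LEN", "JOIN_MISMATCH",
                  "ONLIST_MISSING", "ONLIST_LEN", "MODALITY_MAP",
                  "UNKNOWN_TYPE")

## All fixture randomness flows through one seeded generator; the global
## .Random.seed is saved and restored so package code never leaks RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_seq <- function(n_chars) {
  paste(sample(c("A", "C", "G", "T"), n_chars, replace = TRUE), collapse = "")
}

random_seqs <- function(n, len) {
  vapply(rep(len, length.out = n), random_seq, character(1))
}

#' Configuration for the synthetic fixture generator
#'
#' @param seed Integer seed; identical seed and configuration give
#'   byte-identical fixture output.
#' @param n_modalities Number of modalities, 1-3 (`rna`, then `atac`, then
#'   `tag`).
#' @param leaves_per_modality Number of atomic regions inside the read
#'   containers, 2-8 (flanking adapters are added on top of this count).
#' @param variable_fraction Probability that a barcode/biological leaf is
#'   variable-length.
#' @param onlist_size Sequences per generated barcode onlist.
#' @param defect Optional violation code from [defect_codes()]; the emitted
#'   fixture then breaks exactly that invariant.
#' @return A list of class `"fixture_config"`.
#' @export
fixture_config <- function(seed = 1L, n_modalities = 1L,
                           leaves_per_modality = 3L, variable_fraction = 0,
                           onlist_size = 16L, defect = NULL) {
  stopifnot(n_modalities >= 1L, n_modalities <= 3L,
            leaves_per_modality >= 2L, leaves_per_modality <= 8L,
            variable_fraction >= 0, variable_fraction <= 1,
            onlist_size >= 1L)
  if (!is.null(defect)) {
    if (!defect %in% DEFECT_CODES) {
      stop("unknown defect code: ", defect, call. = FALSE)
    }
    if (defect == "DUP_ID" && leaves_per_modality < 2L) {
      stop("config error: DUP_ID defect needs leaves_per_modality >= 2",
           call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed),
                 n_modalities = as.integer(n_modalities),
                 leaves_per_modality = as.integer(leaves_per_modality),
                 variable_fraction = variable_fraction,
                 onlist_size = as.integer(onlist_size),
                 defect = defect),
            class = "fixture_config")
}

#' Violation codes the fixture generator can inject
#' @return Character vector of the 8 injectable defect codes.
#' @export
defect_codes <- function() DEFECT_CODES

## Insert leaves for one modality: >=1 barcode, biological leaf last; a umi
## from 3 leaves up; extra slots alternate linkers and further barcodes
## (split-pool style).
modality_leaves <- function(m, k, variable_fraction, bio_type) {
  mk_var <- function(len) {
    if (stats::runif(1) < variable_fraction) {
      c(max(1L, len - sample(1:3, 1L)), len)
    } else c(len, len)
  }
  bc_len <- sample(8:16, 1L)
  lens <- mk_var(bc_len)
  lv <- list(region(paste0(m, "-barcode-1"), "barcode",
                    sequence_type = "onlist",
                    min_len = lens[1L], max_len = lens[2L]))
  if (k >= 3L) {
    lv <- c(lv, list(region(paste0(m, "-umi"), "umi",
                            sequence_type = "random",
                            min_len = sample(8:12, 1L))))
  }
  extra <- k - length(lv) - 1L
  i_bc <- 1L
  for (e in seq_len(max(0L, extra))) {
    if (e %% 2L == 1L) {
      len <- sample(4:10, 1L)
      lv <- c(lv, list(region(paste0(m, "-linker-", (e + 1L) %/% 2L),
                              "linker", sequence_type = "fixed",
                              sequence = random_seq(len), min_len = len)))
    } else {
      i_bc <- i_bc + 1L
      lens <- mk_var(sample(6:12, 1L))
      lv <- c(lv, list(region(paste0(m, "-barcode-", i_bc), "barcode",
                              sequence_type = "onlist",
                              min_len = lens[1L], max_len = lens[2L])))
    }
  }
  bio_lens <- mk_var(sample(50:100, 1L))
  c(lv, list(region(paste0(m, "-", bio_type), bio_type,
                    sequence_type = "random",
                    min_len = bio_lens[1L], max_len = bio_lens[2L])))
}

#' Generate a synthetic assay fixture
#'
#' Emits, into a fresh workspace directory, a complete adapter-insert-adapter
#' construct: fixed P5/P7 adapters flanking read containers that hold
#' barcode (onlist), UMI (random), linker (fixed) and cDNA/gDNA (random)
#' regions, together with a generated onlist file per barcode. Without a
#' defect the written spec passes [spec_check()] with zero violations; with
#' `cfg$defect` set, exactly that invariant is broken.
#'
#' @param cfg A [fixture_config()].
#' @param dir Workspace directory (created if needed); defaults to a fresh
#'   temporary directory.
#' @return A list with `assay` (the in-memory document, base dir attached),
#'   `dir`, `spec_path`, and `onlist_paths`.
#' @export
make_fixture <- function(cfg, dir = tempfile("fixture")) {
  stopifnot(inherits(cfg, "fixture_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_local_seed(cfg$seed, {
    mods <- c("rna", "atac", "tag")[seq_len(cfg$n_modalities)]
    onlist_paths <- character()
    trees <- lapply(mods, function(m) {
      bio_type <- if (m == "atac") "gdna" else "cdna"
      lv <- modality_leaves(m, cfg$leaves_per_modality,
                            cfg$variable_fraction, bio_type)
      is_bio <- vapply(lv, function(l) l$region_type == bio_type, logical(1))
      for (i in which(vapply(lv, function(l)
        l$sequence_type == "onlist", logical(1)))) {
        fn <- paste0(lv[[i]]$region_id, "_onlist.txt")
        rng <- seq(lv[[i]]$min_len, lv[[i]]$max_len)
        lens <- if (length(rng) == 1L) rep(rng, cfg$onlist_size) else
          sample(rng, cfg$onlist_size, replace = TRUE)
        seqs <- unique(random_seqs(cfg$onlist_size, lens))
        writeLines(seqs, file.path(dir, fn))
        onlist_paths <<- c(onlist_paths, file.path(dir, fn))
        lv[[i]]$onlist <- onlist_ref(fn)
      }
      read1 <- region(paste0(m, "-R1"), "fastq", sequence_type = "joined",
                      regions = lv[!is_bio])
      read2 <- region(paste0(m, "-R2"), "fastq", sequence_type = "joined",
                      regions = lv[is_bio])
      region(m, m, sequence_type = "joined", regions = list(
        region(paste0(m, "-p5"), "illumina_p5", sequence_type = "fixed",
               sequence = P5_SEQ, min_len = nchar(P5_SEQ)),
        read1, read2,
        region(paste0(m, "-p7"), "illumina_p7", sequence_type = "fixed",
               sequence = P7_SEQ, min_len = nchar(P7_SEQ))
      ))
    })
    a <- assay(
      assay_id = sprintf("synthetic-%d", cfg$seed),
      name = sprintf("synthetic fixture (seed %d)", cfg$seed),
      description = "generated adapter-insert-adapter construct",
      modalities = mods, library_spec = trees
    )
    a <- spec_format(a)
    if (!is.null(cfg$defect)) {
      a <- inject_defect(a, cfg$defect, dir)
    }
    spec_path <- file.path(dir, "spec.yaml")
    write_spec_file(a, spec_path)
    attr(a, "base_dir") <- dir
    list(assay = a, dir = dir, spec_path = spec_path,
         onlist_paths = onlist_paths)
  })
}

## Break exactly one invariant of an otherwise-valid formatted document.
inject_defect <- function(a, code, dir) {
  m <- a$modalities[1L]
  tree <- modality_tree(a, m)
  lv <- leaves(tree)
  insert <- Filter(function(l) !l$region_type %in%
                     c("illumina_p5", "illumina_p7"), lv)
  set_tree <- function(a, tree) {
    a$library_spec[[match(m, a$modalities)]] <- tree
    a
  }
  switch(code,
    DUP_ID = {
      a <- spec_from_edit(a, insert[[2L]]$region_id,
                          list(region_id = insert[[1L]]$region_id))
    },
    LEN_ORDER = {
      l <- insert[[1L]]
      a <- spec_from_edit(a, l$region_id,
                          list(min_len = l$max_len + 1L))
    },
    FIXED_SEQ_LEN = {
      a <- spec_from_edit(a, lv[[1L]]$region_id,
                          list(sequence = substr(lv[[1L]]$sequence, 1L,
                                                 nchar(lv[[1L]]$sequence) - 1L)))
    },
    JOIN_MISMATCH = {
      tree$max_len <- tree$max_len + 1L
      a <- set_tree(a, tree)
    },
    ONLIST_MISSING = {
      bc <- Filter(function(l) l$sequence_type == "onlist", lv)[[1L]]
      a <- spec_from_edit(a, bc$region_id, list(onlist = NULL))
    },
    ONLIST_LEN = {
      bc <- Filter(function(l) l$sequence_type == "onlist", lv)[[1L]]
      path <- file.path(dir, bc$onlist$filename)
      cat(strrep("A", bc$max_len + 5L), "\n", sep = "",
          file = path, append = TRUE)
    },
    MODALITY_MAP = {
      tree$region_id <- paste0(m, "-misnamed")
      a <- set_tree(a, tree)
    },
    UNKNOWN_TYPE = {
      a <- spec_from_edit(a, insert[[1L]]$region_id,
                          list(region_type = "mystery_element"))
    }
  )
  a
}

## Raw field edit without spec_modify's re-format/validation (we *want* the
## document to stay broken).
spec_from_edit <- function(a, region_id, updates) {
  a$library_spec <- lapply(a$library_spec, function(tree) {
    edit_region_raw(tree, region_id, updates)
  })
  a
}

edit_region_raw <- function(r, region_id, updates) {
  if (r$region_id == region_id) {
    for (k in names(updates)) r[k] <- list(updates[[k]])
    return(r)
  }
  r$regions <- lapply(r$regions, edit_region_raw, region_id = region_id,
                      updates = updates)
  r
}
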