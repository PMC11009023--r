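## Vectorized random sequences: n strings with per-string lengths `lens`.
random_seqs_vec <- function(lens) {
  total <- sum(lens)
  if (total == 0L) return(rep("", length(lens)))
  chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  out <- character(length(lens))
  big <- paste(chars, collapse = "")
  for (i in seq_along(lens)) {
    out[i] <- if (lens[i] == 0L) "" else substr(big, starts[i], ends[i])
  }
  out
}

## Independent per-base substitutions at `rate`; a hit base is replaced by
## one of the three *other* bases, so `rate` is the realized mismatch
## probability per base.
apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  lens <- nchar(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(stats::runif(length(flat)) < rate)
  if (length(hit) > 0L) {
    pick <- sample.int(3L, length(hit), replace = TRUE)
    flat[hit] <- mapply(function(b, p) alts[[b]][p], flat[hit], pick,
                        USE.NAMES = FALSE)
  }
  grp <- factor(rep(seq_along(seqs), lens), levels = seq_along(seqs))
  unname(vapply(split(flat, grp), paste, character(1), collapse = ""))
}

#' Simulate reads from a library specification
#'
#' Draws `n` idealized library molecules from the construct (perfect
#' end-to-end sequencing of a perfectly constructed library): onlist regions
#' draw uniformly from their onlist, random regions draw uniform `A/C/G/T`
#' sequence with length uniform on `[min_len, max_len]`, fixed regions
#' contribute their sequence verbatim. The 5' to 3' concatenation is then
#' sliced at read-container (`region_type = "fastq"`) boundaries into one
#' FASTQ record set per read, and independent per-base substitutions are
#' applied at `error_rate` (a substituted base always differs from the
#' original; there are no indels). Qualities are constant `I` (Phred+33
#' score 40).
#'
#' @param assay A valid [assay()] whose barcode regions carry local onlists.
#' @param modality One of `assay$modalities`.
#' @param n Number of molecules.
#' @param seed Integer seed (all randomness is local to this call).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param dir Base directory for relative onlist paths.
#' @return A named list, one element per read container in 5' to 3' order;
#'   each element is a data frame with columns `id`, `sequence`, `quality`.
#' @export
simulate_reads <- function(assay, modality, n, seed = 1L, error_rate = 0,
                           dir = attr(assay, "base_dir")) {
  stopifnot(inherits(assay, "assay"), n >= 1L)
  tree <- modality_tree(assay, modality)
  lv <- leaves(tree)
  containers <- read_containers(assay, modality)
  with_local_seed(seed, {
    realized <- lapply(lv, function(l) {
      switch(l$sequence_type,
        fixed = rep(l$sequence, n),
        onlist = {
          seqs <- read_onlist(l$onlist, dir)
          seqs[sample.int(length(seqs), n, replace = TRUE)]
        },
        random = {
          rng <- seq(l$min_len, l$max_len)
          lens <- if (length(rng) == 1L) rep(rng, n) else
            sample(rng, n, replace = TRUE)
          random_seqs_vec(lens)
        },
        stop(sprintf("cannot simulate leaf '%s' with sequence_type '%s'",
                     l$region_id, l$sequence_type), call. = FALSE)
      )
    })
    names(realized) <- vapply(lv, function(l) l$region_id, character(1))
    ids <- sprintf("molecule_%d", seq_len(n))
    out <- lapply(seq_along(containers), function(ci) {
      leaf_ids <- vapply(leaves(containers[[ci]]), function(l) l$region_id,
                         character(1))
      seqs <- do.call(paste0, realized[leaf_ids])
      seqs <- apply_errors(seqs, error_rate)
      data.frame(id = ids, sequence = seqs,
                 quality = strrep("I", nchar(seqs)),
                 stringsAsFactors = FALSE)
    })
    names(out) <- vapply(containers, function(r) r$region_id, character(1))
    out
  })
}

#' Write FASTQ records
#'
#' Standard 4-line records (Phred+33). A `.gz` suffix triggers gzip
#' compression.
#'
#' @param records Data frame with columns `id`, `sequence`, `quality` (as
#'   produced by [simulate_reads()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(records)))
  lines <- as.vector(rbind(paste0("@", records$id), records$sequence,
                           "+", records$quality))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read FASTQ records
#'
#' @param path A FASTQ file (optionally gzip-compressed).
#' @return Data frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: line count not a multiple of 4", call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 4L)
  data.frame(id = sub("^@", "", lines[idx]), sequence = lines[idx + 1L],
             quality = lines[idx + 3L], stringsAsFactors = FALSE)
}
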