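## Read containers are regions of region_type "fastq", numbered 1..R in
## 5'-to-3' pre-order; element offsets are computed relative to the
## containing read (coordinates restart at 0 at each read boundary), which
## is how all three supported preprocessors address reads.

read_containers <- function(assay, modality) {
  containers <- find_by_type(assay, modality, "fastq")
  if (length(containers) == 0L) {
    stop(sprintf("modality '%s' has no read containers (region_type 'fastq')",
                 modality), call. = FALSE)
  }
  containers
}

## Per-read element table: read (1-based), region_id, region_type,
## read-relative start/stop (0-based half-open, both length tracks), fixed.
read_layout <- function(assay, modality) {
  containers <- read_containers(assay, modality)
  rows <- lapply(seq_along(containers), function(i) {
    lv <- leaves(containers[[i]])
    cmin <- 0L; cmax <- 0L; rigid <- TRUE
    do.call(rbind, lapply(lv, function(l) {
      row <- data.frame(
        read = i, region_id = l$region_id, region_type = l$region_type,
        start_min = cmin, start_max = cmax,
        stop_min = cmin + l$min_len, stop_max = cmax + l$max_len,
        fixed = rigid && l$min_len == l$max_len,
        last_in_read = FALSE, stringsAsFactors = FALSE)
      cmin <<- cmin + l$min_len
      cmax <<- cmax + l$max_len
      rigid <<- rigid && l$min_len == l$max_len
      row
    })) -> df
    df$last_in_read[nrow(df)] <- TRUE
    df
  })
  do.call(rbind, rows)
}

#' Emit a preprocessing-tool technology string
#'
#' Converts the read-relative layout of barcode, UMI, and cDNA elements into
#' the geometry-string dialect of one of three single-cell RNA-seq
#' preprocessors. The modality must contain, inside its read containers, at
#' least one barcode, exactly one UMI, and exactly one cDNA leaf; barcode
#' and UMI intervals must be fixed -- variable-length barcode designs (such
#' as inDrops-style split barcodes) have no constant read offsets and are
#' rejected with a geometry error.
#'
#' Dialects:
#' * `kb` (kallisto|bustools): colon-separated `read,start,stop` triplets,
#'   0-based half-open, ordered barcode(s), UMI, cDNA; the cDNA group uses
#'   `stop = 0` meaning "to the end of the read", e.g.
#'   `"0,0,16:0,16,28:1,0,0"`.
#' * `starsolo`: `--soloCBstart/--soloCBlen/--soloUMIstart/--soloUMIlen`
#'   flags with 1-based starts; multiple barcodes are concatenated into the
#'   cell barcode only when adjacent in the same read.
#' * `simpleaf` (alevin-fry): per-read blocks `N{...}` holding `b[len]`
#'   (barcode), `u[len]` (UMI), `r` (biological rest-of-read), `x[len]`
#'   (skip) in 5' to 3' order, e.g. `"1{b[16]u[12]}2{r}"`.
#'
#' Every length embedded in an emitted string equals `stop - start` of the
#' corresponding [spec_index()] interval, and STARsolo's 1-based starts are
#' the kb 0-based starts plus one.
#'
#' @param assay An [assay()].
#' @param modality One of `assay$modalities`.
#' @param tool `"kb"`, `"starsolo"`, or `"simpleaf"`.
#' @return An object of class `"tool_geometry"`: list with `tool`, `text`,
#'   and `warnings` (character vector).
#' @export
emit_geometry <- function(assay, modality, tool = c("kb", "starsolo", "simpleaf")) {
  tool <- match.arg(tool)
  layout <- read_layout(assay, modality)
  bc <- layout[layout$region_type == "barcode", , drop = FALSE]
  umi <- layout[layout$region_type == "umi", , drop = FALSE]
  bio <- layout[layout$region_type %in% c("cdna", "gdna"), , drop = FALSE]
  if (nrow(bc) < 1L || nrow(umi) != 1L || nrow(bio) != 1L) {
    stop(sprintf(paste0("structure error: need >=1 barcode, exactly 1 umi and ",
                        "1 cdna leaf inside read containers; found %d barcode, ",
                        "%d umi, %d cdna/gdna"),
                 nrow(bc), nrow(umi), nrow(bio)), call. = FALSE)
  }
  techy <- rbind(bc, umi)
  if (any(!techy$fixed)) {
    culprit <- techy$region_id[!techy$fixed][1L]
    stop(sprintf(paste0("geometry error: interval of '%s' is variable ",
                        "(inDropsv3-style variable-length elements have no ",
                        "fixed read offsets); cannot emit a fixed-geometry ",
                        "technology string"), culprit), call. = FALSE)
  }
  warnings <- character()
  text <- switch(tool,
    kb = emit_kb(bc, umi, bio),
    starsolo = emit_starsolo(bc, umi),
    simpleaf = emit_simpleaf(layout)
  )
  structure(list(tool = tool, text = text, warnings = warnings),
            class = "tool_geometry")
}

emit_kb <- function(bc, umi, bio) {
  triplet <- function(row) sprintf("%d,%d,%d", row$read - 1L,
                                   row$start_min, row$stop_min)
  groups <- c(
    vapply(seq_len(nrow(bc)), function(i) triplet(bc[i, ]), character(1)),
    triplet(umi[1L, ]),
    sprintf("%d,%d,0", bio$read[1L] - 1L, bio$start_min[1L])
  )
  paste(groups, collapse = ":")
}

emit_starsolo <- function(bc, umi) {
  if (nrow(bc) > 1L) {
    same_read <- all(bc$read == bc$read[1L])
    adjacent <- all(bc$start_min[-1L] == bc$stop_min[-nrow(bc)])
    if (!same_read || !adjacent) {
      stop(paste0("geometry error: STARsolo concatenates multiple barcodes ",
                  "into the cell barcode only when they are adjacent in the ",
                  "same read"), call. = FALSE)
    }
  }
  cb_start <- bc$start_min[1L] + 1L
  cb_len <- sum(bc$stop_min - bc$start_min)
  sprintf("--soloCBstart %d --soloCBlen %d --soloUMIstart %d --soloUMIlen %d",
          cb_start, cb_len, umi$start_min[1L] + 1L,
          umi$stop_min[1L] - umi$start_min[1L])
}

emit_simpleaf <- function(layout) {
  blocks <- vapply(sort(unique(layout$read)), function(rd) {
    rows <- layout[layout$read == rd, , drop = FALSE]
    parts <- vapply(seq_len(nrow(rows)), function(i) {
      row <- rows[i, ]
      len <- row$stop_min - row$start_min
      if (row$region_type == "barcode") return(sprintf("b[%d]", len))
      if (row$region_type == "umi") return(sprintf("u[%d]", len))
      if (row$region_type %in% c("cdna", "gdna")) return("r")
      if (!row$fixed || row$stop_min - row$start_min !=
          row$stop_max - row$start_max) {
        stop(sprintf("geometry error: cannot express variable-length '%s' as a skip",
                     row$region_id), call. = FALSE)
      }
      sprintf("x[%d]", len)
    }, character(1))
    sprintf("%d{%s}", rd, paste(parts, collapse = ""))
  }, character(1))
  paste(blocks, collapse = "")
}

#' @export
print.tool_geometry <- function(x, ...) {
  cat(sprintf("<%s> %s\n", x$tool, x$text))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}
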