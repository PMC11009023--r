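leaf_label <- function(l, max_chars = 20L) {
  len <- if (l$min_len == l$max_len) as.character(l$min_len) else
    paste0(l$min_len, "-", l$max_len)
  id <- l$region_id
  if (nchar(id) > max_chars) id <- paste0(substr(id, 1L, max_chars - 2L), "..")
  sprintf("%s(%s)", id, len)
}

#' Render an assay as a diagram or table
#'
#' Three formats:
#' * `ascii` -- a read diagram: one banner per modality followed by a
#'   left-to-right row of boxes, one box per atomic region in 5' to 3'
#'   order, labeled `region_id(len)` (with `min-max` for variable lengths).
#'   When read containers (`region_type = "fastq"`) are present, bracket
#'   lines above the boxes mark which boxes each read covers. Box rows wrap
#'   to respect `width`; labels longer than 20 characters are truncated with
#'   `..`.
#' * `markdown` -- one table per modality with columns order, region_id,
#'   region_type, lengths, sequence.
#' * `html` -- the same tables wrapped in a minimal standalone page.
#'
#' Output is deterministic.
#'
#' @param assay An [assay()].
#' @param format `"ascii"`, `"markdown"`, or `"html"`.
#' @param width Maximum line width in columns (ascii only, `>= 40`).
#' @return A single string.
#' @export
render_spec <- function(assay, format = c("ascii", "markdown", "html"),
                        width = 80L) {
  format <- match.arg(format)
  stopifnot(inherits(assay, "assay"))
  switch(format,
    ascii = render_ascii(assay, as.integer(width)),
    markdown = render_markdown(assay),
    html = render_html(assay)
  )
}

render_ascii <- function(assay, width) {
  if (width < 40L) stop("ascii rendering needs width >= 40", call. = FALSE)
  out <- character()
  for (m in assay$modalities) {
    tree <- modality_tree(assay, m)
    lv <- leaves(tree)
    labs <- vapply(lv, leaf_label, character(1))
    if (any(nchar(labs) + 2L > width)) {
      stop(sprintf("rendering error: label '%s' does not fit in width %d; use a larger width",
                   labs[which.max(nchar(labs))], width), call. = FALSE)
    }
    reads <- leaf_read_membership(tree)
    out <- c(out, sprintf("=== %s ===", m),
             box_banks(labs, reads, width), "")
  }
  paste(c(out, ""), collapse = "\n")
}

## For each leaf, the 1-based index of the fastq container holding it, or
## NA when it lies outside every read (e.g. flanking adapters).
leaf_read_membership <- function(tree) {
  containers <- Filter(function(n) n$region$region_type == "fastq",
                       walk_regions(tree))
  member <- rep(NA_integer_, length(leaves(tree)))
  all_ids <- vapply(leaves(tree), function(l) l$region_id, character(1))
  for (i in seq_along(containers)) {
    ids <- vapply(leaves(containers[[i]]$region), function(l) l$region_id,
                  character(1))
    member[all_ids %in% ids] <- i
  }
  member
}

## Lay boxes out left to right, wrapping into banks of <= width columns;
## each bank gets border / label / border lines plus, when any leaf sits in
## a read container, a bracket line naming the reads it spans.
box_banks <- function(labs, reads, width) {
  widths <- nchar(labs)
  banks <- list()
  i <- 1L
  while (i <= length(labs)) {
    j <- i
    used <- widths[i] + 2L
    while (j < length(labs) && used + widths[j + 1L] + 1L <= width) {
      j <- j + 1L
      used <- used + widths[j] + 1L
    }
    banks <- c(banks, list(i:j))
    i <- j + 1L
  }
  lines <- character()
  for (bank in banks) {
    w <- widths[bank]
    border <- paste0("+", paste(strrep("-", w), collapse = "+"), "+")
    body <- paste0("|", paste(labs[bank], collapse = "|"), "|")
    rd <- reads[bank]
    if (any(!is.na(rd))) {
      seg <- character()
      k <- 1L
      while (k <= length(bank)) {
        if (is.na(rd[k])) {
          seg <- c(seg, strrep(" ", w[k] + 1L))
          k <- k + 1L
        } else {
          k2 <- k
          while (k2 < length(bank) && !is.na(rd[k2 + 1L]) &&
                 rd[k2 + 1L] == rd[k]) k2 <- k2 + 1L
          span <- sum(w[k:k2]) + (k2 - k)
          tag <- sprintf(" read%d ", rd[k])
          if (nchar(tag) + 2L > span) tag <- ""
          pad <- span - 2L - nchar(tag)
          seg <- c(seg, paste0(
            "[", strrep("-", ceiling(pad / 2)), tag,
            strrep("-", floor(pad / 2)), "]", " "))
          k <- k2 + 1L
        }
      }
      lines <- c(lines, substr(paste(seg, collapse = ""), 1L,
                               nchar(border)))
    }
    lines <- c(lines, border, body, border)
  }
  lines
}

modality_table <- function(assay, m) {
  lv <- leaves(modality_tree(assay, m))
  data.frame(
    order = seq_along(lv),
    region_id = vapply(lv, function(l) l$region_id, character(1)),
    region_type = vapply(lv, function(l) l$region_type, character(1)),
    lengths = vapply(lv, function(l) {
      if (l$min_len == l$max_len) as.character(l$min_len) else
        paste0(l$min_len, "-", l$max_len)
    }, character(1)),
    sequence = vapply(lv, function(l) l$sequence, character(1)),
    stringsAsFactors = FALSE
  )
}

render_markdown <- function(assay) {
  out <- character()
  for (m in assay$modalities) {
    df <- modality_table(assay, m)
    out <- c(out, sprintf("## %s", m), "",
             "| order | region_id | region_type | lengths | sequence |",
             "|---|---|---|---|---|",
             vapply(seq_len(nrow(df)), function(i) {
               paste0("| ", paste(unlist(df[i, ]), collapse = " | "), " |")
             }, character(1)), "")
  }
  paste(c(out, ""), collapse = "\n")
}

render_html <- function(assay) {
  body <- character()
  for (m in assay$modalities) {
    df <- modality_table(assay, m)
    rows <- vapply(seq_len(nrow(df)), function(i) {
      paste0("<tr>", paste0("<td>", unlist(df[i, ]), "</td>", collapse = ""),
             "</tr>")
    }, character(1))
    body <- c(body, sprintf("<h2>%s</h2>", m), "<table>",
              "<tr><th>order</th><th>region_id</th><th>region_type</th><th>lengths</th><th>sequence</th></tr>",
              rows, "</table>")
  }
  paste(c("<!DOCTYPE html>", "<html>",
          sprintf("<head><title>%s</title></head>", assay$name),
          "<body>", sprintf("<h1>%s</h1>", assay$name), body,
          "</body>", "</html>", ""), collapse = "\n")
}
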