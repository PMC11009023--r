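# Independent oracles and generators used across the suite. Each oracle is
# deliberately written as the most naive possible computation, sharing no
# code with the implementation paths it checks.

## Brute-force recursive flatten: collect childless nodes left to right.
oracle_flatten <- function(r) {
  if (length(r$regions) == 0L) return(list(r))
  out <- list()
  for (ch in r$regions) out <- c(out, oracle_flatten(ch))
  out
}

## Exhaustive full-tree scan for a region id (returns count and region).
oracle_scan_id <- function(assay, id) {
  hits <- list()
  visit <- function(r) {
    if (r$region_id == id) hits[[length(hits) + 1L]] <<- r
    for (ch in r$regions) visit(ch)
  }
  for (t in assay$library_spec) visit(t)
  hits
}

## Independent recursive sum/concat routine for joined metadata.
oracle_resolve <- function(r) {
  if (length(r$regions) == 0L) {
    seq <- switch(r$sequence_type,
      random = strrep("X", r$max_len),
      onlist = if (nzchar(r$sequence)) r$sequence else strrep("N", r$max_len),
      r$sequence)
    return(list(seq = seq, min = r$min_len, max = r$max_len))
  }
  parts <- lapply(r$regions, oracle_resolve)
  list(seq = paste(vapply(parts, `[[`, character(1), "seq"), collapse = ""),
       min = sum(vapply(parts, `[[`, numeric(1), "min")),
       max = sum(vapply(parts, `[[`, numeric(1), "max")))
}

## Exhaustive interval oracle: materialize every concrete length assignment
## within [min, max] per leaf and take min/max of the realized offsets.
## Feasible for <= 8 leaves with per-leaf range width <= 3.
oracle_index <- function(mins, maxs) {
  choices <- lapply(seq_along(mins), function(i) seq(mins[i], maxs[i]))
  grid <- expand.grid(choices)
  n <- length(mins)
  res <- data.frame(start_min = rep(NA_integer_, n), start_max = NA_integer_,
                    stop_min = NA_integer_, stop_max = NA_integer_,
                    fixed = NA)
  for (i in seq_len(n)) {
    starts <- if (i == 1L) rep(0L, nrow(grid)) else
      as.integer(rowSums(grid[, seq_len(i - 1L), drop = FALSE]))
    stops <- starts + grid[[i]]
    res$start_min[i] <- min(starts); res$start_max[i] <- max(starts)
    res$stop_min[i] <- min(stops);   res$stop_max[i] <- max(stops)
    res$fixed[i] <- length(unique(starts)) == 1L && length(unique(stops)) == 1L
  }
  res
}

## Random region tree for property tests: nested shape, small length
## ranges, unique ids. Returns a single-modality assay.
random_tree_assay <- function(seed, max_leaves = 8L, max_range = 2L) {
  set.seed(seed)
  counter <- 0L
  new_id <- function(p) { counter <<- counter + 1L; sprintf("%s%d", p, counter) }
  make_leaf <- function() {
    mn <- sample(0:9, 1L)
    mx <- mn + sample(0:max_range, 1L)
    if (mn == mx && mn > 0L && stats::runif(1) < 0.4) {
      region(new_id("fx"), "linker", sequence_type = "fixed",
             sequence = paste(sample(c("A", "C", "G", "T"), mn, replace = TRUE),
                              collapse = ""), min_len = mn, max_len = mx)
    } else {
      region(new_id("rd"), "custom", sequence_type = "random",
             min_len = mn, max_len = mx)
    }
  }
  n_leaves <- sample(1:max_leaves, 1L)
  leaves_list <- replicate(n_leaves, make_leaf(), simplify = FALSE)
  ## randomly group consecutive leaves under meta nodes (possibly nested)
  group <- function(nodes) {
    if (length(nodes) <= 1L) return(nodes)
    out <- list()
    i <- 1L
    while (i <= length(nodes)) {
      take <- min(sample(1:3, 1L), length(nodes) - i + 1L)
      chunk <- nodes[i:(i + take - 1L)]
      if (take > 1L && stats::runif(1) < 0.5) {
        out <- c(out, list(region(new_id("meta"), "custom",
                                  sequence_type = "joined", regions = chunk)))
      } else {
        out <- c(out, chunk)
      }
      i <- i + take
    }
    if (length(out) < length(nodes) && stats::runif(1) < 0.3) group(out) else out
  }
  top <- region("mod1", "rna", sequence_type = "joined",
                regions = group(leaves_list))
  spec_format(assay(sprintf("rand-%d", seed), "random tree",
                    modalities = "mod1", library_spec = list(top)))
}

toy1 <- function() example_assay("tenx-like")
toy2 <- function() example_assay("indrops-like")
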