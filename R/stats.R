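## Cohort descriptive statistics: grading table (counts + percentages),
## Spearman rank correlation with the t approximation, Cohen's kappa, and
## machine-readable report output.

pct1 <- function(k, n) round(100 * k / n, 1)  # round-half-even, 1 decimal

#' Build the cohort grading table
#'
#' Aggregates grading records into counts and percentages per axis: vessel
#' branch histogram (1..4, 5+), plexus origin, retinal layer occupancy
#' (multi-membership, so the layer counts may sum past the total), shape and
#' orientation classes, plus mean vessels per lesion and median size.
#' Percentages are `round(100*k/n, 1)` (round-half-even).
#'
#' @param records list of `ma_record`s (see [grade_ma()]) or a data.frame
#'   from [records_df()]. Aborted records are dropped.
#' @return an object of class `grading_table`.
#' @export
build_table <- function(records) {
  df <- if (is.data.frame(records)) records else records_df(records)
  df <- df[df$status == "ok", , drop = FALSE]
  if (!nrow(df)) stop("no graded records to tabulate")
  n <- nrow(df)
  vh <- vapply(1:4, function(k) sum(df$n_vessels == k), 0L)
  vh <- c(vh, sum(df$n_vessels >= 5))
  names(vh) <- c("1", "2", "3", "4", "5+")
  origin <- vapply(c("SCP_only", "DVC_only", "both"),
                   function(o) sum(df$origin_class == o), 0L)
  layer_sets <- strsplit(df$layers, ",", fixed = TRUE)
  layers <- vapply(LAYER_NAMES, function(L)
    sum(vapply(layer_sets, function(s) L %in% s, TRUE)), 0L)
  shape <- vapply(c("saccular", "fusiform", "focal_bulge"),
                  function(s) sum(df$shape_class == s), 0L)
  orientation <- vapply(c("parallel", "oblique"),
                        function(o) sum(df$orientation_class == o), 0L)
  structure(list(
    n_total = n,
    vessel_counts = vh, vessel_pct = pct1(vh, n),
    origin_counts = origin, origin_pct = pct1(origin, n),
    layer_counts = layers, layer_pct = pct1(layers, n),
    shape_counts = shape, shape_pct = pct1(shape, n),
    orientation_counts = orientation, orientation_pct = pct1(orientation, n),
    mean_vessels = round(mean(df$n_vessels), 1),
    median_size_um = round(median(df$size_um), 1)
  ), class = "grading_table")
}

#' @export
print.grading_table <- function(x, ...) {
  cat(sprintf("grading_table: %d MAs\n", x$n_total))
  line <- function(lbl, cnt, pct)
    for (nm in names(cnt))
      cat(sprintf("  %-12s %-12s %3d (%.1f%%)\n", lbl, nm, cnt[[nm]],
                  pct[[nm]]))
  line("vessels", x$vessel_counts, x$vessel_pct)
  line("origin", x$origin_counts, x$origin_pct)
  line("layer", x$layer_counts, x$layer_pct)
  line("shape", x$shape_counts, x$shape_pct)
  line("orientation", x$orientation_counts, x$orientation_pct)
  cat(sprintf("  mean vessels %.1f, median size %.1f um\n",
              x$mean_vessels, x$median_size_um))
  invisible(x)
}

#' Reconstruct per-axis grading records from marginal counts
#'
#' Builds a records data.frame whose per-axis marginals match the given count
#' vectors, for arithmetic checks of [build_table()] against published count
#' tables. Axes are assigned independently (the joint distribution is not
#' recoverable from marginals and does not affect any per-axis statistic).
#' Layer membership is assigned in contiguous runs arranged so every record
#' occupies at least one layer.
#'
#' @param vessel_counts named vector, counts for 1..4 vessels.
#' @param origin_counts named vector for SCP_only/DVC_only/both.
#' @param layer_counts named vector for GCC/INL/OPL/ONL (multi-membership).
#' @param shape_counts named vector for saccular/fusiform/focal_bulge.
#' @param orientation_counts named vector for parallel/oblique.
#' @param sizes_um optional vector of sizes (recycled to n).
#' @return data.frame suitable for [build_table()].
#' @export
records_from_counts <- function(vessel_counts, origin_counts, layer_counts,
                                shape_counts, orientation_counts,
                                sizes_um = 100) {
  n <- sum(vessel_counts)
  stopifnot(sum(origin_counts) == n, sum(shape_counts) == n,
            sum(orientation_counts) == n, all(layer_counts <= n))
  expand <- function(cnt) rep(names(cnt), times = cnt)
  member <- function(k, anchor_end) {
    ## k members as a contiguous run, anchored to the start or end
    if (k == 0) return(rep(FALSE, n))
    if (anchor_end) c(rep(FALSE, n - k), rep(TRUE, k))
    else c(rep(TRUE, k), rep(FALSE, n))[seq_len(n)]
  }
  gcc <- member(layer_counts[["GCC"]], FALSE)
  inl <- member(layer_counts[["INL"]], FALSE)
  opl <- member(layer_counts[["OPL"]], TRUE)
  onl <- member(layer_counts[["ONL"]], TRUE)
  if (any(!(gcc | inl | opl | onl)))
    stop("layer counts leave some records with no layer")
  layers <- vapply(seq_len(n), function(i)
    paste(LAYER_NAMES[c(gcc[i], inl[i], opl[i], onl[i])], collapse = ","), "")
  data.frame(
    id = seq_len(n), status = "ok",
    n_vessels = as.integer(expand(vessel_counts)),
    origin_class = expand(origin_counts),
    layers = layers,
    n_layers = vapply(strsplit(layers, ","), length, 0L),
    shape_class = expand(shape_counts),
    orientation_class = expand(orientation_counts),
    size_um = rep_len(sizes_um, n),
    stringsAsFactors = FALSE)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Mid-ranks are used for ties; rho is the Pearson correlation of the ranks,
#' and the two-sided p-value comes from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` against a t distribution with
#' n - 2 degrees of freedom. With `exact = TRUE` (n <= 10, no ties needed) a
#' full permutation p-value is computed instead.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param exact use the exact permutation distribution (n <= 10 only).
#' @return list with `rho`, `p_value`, `n`, and `defined` (FALSE when either
#'   ranking has zero variance).
#' @export
spearman_corr <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal-length vectors, n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  p <- if (exact) {
    if (n > 10) stop("exact permutation p only for n <= 10")
    perms <- perm_all(n)
    obs <- abs(rho)
    cnt <- 0L
    for (k in seq_len(nrow(perms))) {
      ryp <- ry[perms[k, ]]
      r <- sum((rx - mean(rx)) * (ryp - mean(ryp))) /
        sqrt(sum((rx - mean(rx))^2) * sum((ryp - mean(ryp))^2))
      if (abs(r) >= obs - 1e-12) cnt <- cnt + 1L
    }
    cnt / nrow(perms)
  } else if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, defined = TRUE)
}

perm_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_all(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Cohen's kappa for two raters
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the
#' marginal label frequencies. Perfect agreement returns exactly 1. When both
#' raters are constant and identical, `p_e = 1` and kappa is defined as 1 by
#' convention, with `degenerate = TRUE`.
#'
#' @param rater_a,rater_b equal-length label vectors.
#' @return list with `kappa`, `n_items`, `categories`, `degenerate`.
#' @export
cohens_kappa <- function(rater_a, rater_b) {
  n <- length(rater_a)
  if (length(rater_b) != n || n == 0) stop("need equal-length label vectors")
  a <- as.character(rater_a); b <- as.character(rater_b)
  cats <- sort(unique(c(a, b)))
  p_o <- mean(a == b)
  pa <- vapply(cats, function(cc) mean(a == cc), 0)
  pb <- vapply(cats, function(cc) mean(b == cc), 0)
  p_e <- sum(pa * pb)
  if (p_e >= 1 - 1e-12)
    return(list(kappa = 1.0, n_items = n, categories = cats,
                degenerate = TRUE))
  k <- if (p_o >= 1) 1.0 else (p_o - p_e) / (1 - p_e)
  list(kappa = k, n_items = n, categories = cats, degenerate = FALSE)
}

#' Write the cohort report to disk
#'
#' Emits `report.json` (full table, correlations, kappa) and `table.csv`
#' (one row per table entry, mirroring the cohort-characteristics layout).
#'
#' @param table a [build_table()] result.
#' @param correlations named list of [spearman_corr()] results (may be
#'   empty).
#' @param kappa a [cohens_kappa()] result or NULL.
#' @param path output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(table, correlations = list(), kappa = NULL, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jpath <- file.path(path, "report.json")
  cpath <- file.path(path, "table.csv")
  tab <- lapply(unclass(table), function(x)
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(
    list(table = tab, correlations = correlations, kappa = kappa),
    jpath, auto_unbox = TRUE, digits = NA, null = "null")
  rows <- rbind(
    data.frame(axis = "total", category = "all", count = table$n_total,
               pct = 100.0),
    data.frame(axis = "vessels", category = names(table$vessel_counts),
               count = as.integer(table$vessel_counts),
               pct = as.numeric(table$vessel_pct)),
    data.frame(axis = "origin", category = names(table$origin_counts),
               count = as.integer(table$origin_counts),
               pct = as.numeric(table$origin_pct)),
    data.frame(axis = "layer", category = names(table$layer_counts),
               count = as.integer(table$layer_counts),
               pct = as.numeric(table$layer_pct)),
    data.frame(axis = "shape", category = names(table$shape_counts),
               count = as.integer(table$shape_counts),
               pct = as.numeric(table$shape_pct)),
    data.frame(axis = "orientation",
               category = names(table$orientation_counts),
               count = as.integer(table$orientation_counts),
               pct = as.numeric(table$orientation_pct)))
  utils::write.csv(rows, cpath, row.names = FALSE)
  invisible(c(jpath, cpath))
}
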