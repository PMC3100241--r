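#' Classify a spine shape class as mature or immature
#'
#' The 8-class spine morphology scale splits into immature shapes (classes
#' 1-5: filopodia-like through thin protrusions) and mature shapes (classes
#' 6-8: mushroom-like and stubby forms).
#'
#' @param shape_class integer vector of classes in 1..8.
#' @return character vector, `"immature"` or `"mature"`.
#' @export
classify_maturity <- function(shape_class) {
  if (!length(shape_class)) return(character(0))
  if (any(is.na(shape_class)) || any(shape_class < 1) || any(shape_class > 8) ||
      any(shape_class != as.integer(shape_class))) {
    stop_param("shape_class must be integers in 1..8")
  }
  ifelse(shape_class >= 6, "mature", "immature")
}

#' Per-cell spine proportions
#'
#' Relative class frequencies, the mature proportion (classes 6-8) and the
#' PSD-95 colocalization proportion for one cell. Spines with a missing
#' PSD-95 flag are excluded from that denominator; if all flags are missing
#' the proportion is `NA`.
#'
#' @param records data.frame of one cell's spines with columns `shape_class`
#'   and optionally `psd95` (logical) and `cell_id`/`condition`.
#' @return object of class `cell_spine_summary`: `cell_id`, `n_spines`,
#'   `class_proportions` (8-vector summing to 1), `prop_mature`,
#'   `prop_psd95`.
#' @export
cell_proportions <- function(records) {
  stopifnot(is.data.frame(records), "shape_class" %in% names(records))
  if (nrow(records) == 0) stop_param("cell has zero spines")
  if (length(unique(records$cell_id)) > 1) {
    stop_param("cell_proportions expects records from a single cell")
  }
  maturity <- classify_maturity(records$shape_class)
  props <- tabulate(records$shape_class, nbins = 8) / nrow(records)
  psd <- if ("psd95" %in% names(records)) records$psd95[!is.na(records$psd95)] else logical(0)
  structure(list(
    cell_id = if ("cell_id" %in% names(records)) records$cell_id[1] else NA,
    condition = if ("condition" %in% names(records)) records$condition[1] else NA,
    n_spines = nrow(records),
    class_proportions = props,
    prop_mature = mean(maturity == "mature"),
    prop_psd95 = if (length(psd)) mean(psd) else NA_real_
  ), class = "cell_spine_summary")
}

#' @export
print.cell_spine_summary <- function(x, ...) {
  cat(sprintf("Cell %s: %d spines, %.2f mature%s\n", x$cell_id, x$n_spines,
              x$prop_mature,
              if (!is.na(x$prop_psd95)) sprintf(", %.2f PSD-95+", x$prop_psd95) else ""))
  invisible(x)
}

#' Per-cell summary table for a spine record table
#'
#' @param records data.frame `(cell_id, condition, shape_class, psd95)`.
#' @return data.frame with one row per cell: `cell_id`, `condition`,
#'   `n_spines`, `prop_class1` .. `prop_class8`, `prop_mature`, `prop_psd95`.
#' @export
spine_cell_table <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("cell_id", "shape_class") %in% names(records)))
  if (nrow(records) == 0) stop_param("no spine records")
  ## cells are nested in conditions: the same cell id may recur across
  ## conditions, so split on both
  key <- if ("condition" %in% names(records)) {
    interaction(records$condition, records$cell_id, drop = TRUE)
  } else {
    records$cell_id
  }
  parts <- lapply(split(records, key), function(df) {
    s <- cell_proportions(df)
    row <- data.frame(cell_id = s$cell_id, condition = s$condition,
                      n_spines = s$n_spines)
    cls <- as.data.frame(as.list(s$class_proportions))
    names(cls) <- paste0("prop_class", 1:8)
    cbind(row, cls, prop_mature = s$prop_mature, prop_psd95 = s$prop_psd95)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Compare spine maturity between conditions
#'
#' The cell is the unit of analysis: per-cell proportions are computed first,
#' then averaged within condition (mean +/- SEM per shape class, for the
#' mature total, and for PSD-95 colocalization), and the mature proportions
#' are compared across conditions by one-way ANOVA. PSD-95 proportions are
#' summarized descriptively only (group means and difference, no test),
#' since the colocalization shift is reported as a trend.
#'
#' @param records data.frame `(cell_id, condition, shape_class, psd95)`
#'   covering >= 2 conditions with >= 2 cells each.
#' @return object of class `spine_comparison`: `cells` (per-cell table),
#'   `group_means` (per condition: n_cells, per-class means and SEMs,
#'   mature and PSD-95 means and SEMs), and `anova_mature`
#'   (a `group_comparison` on per-cell mature proportions).
#' @export
group_spine_comparison <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("cell_id", "condition", "shape_class") %in% names(records)))
  cells <- spine_cell_table(records)
  conds <- split(cells, cells$condition)
  if (length(conds) < 2) stop_param("need >= 2 conditions")
  if (any(vapply(conds, nrow, 1L) < 2)) {
    stop_param("every condition needs >= 2 cells")
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  group_means <- do.call(rbind, lapply(conds, function(df) {
    cls_m <- colMeans(df[paste0("prop_class", 1:8)])
    cls_s <- vapply(df[paste0("prop_class", 1:8)], sem, numeric(1))
    psd <- df$prop_psd95[!is.na(df$prop_psd95)]
    out <- data.frame(condition = df$condition[1], n_cells = nrow(df),
                      mean_prop_mature = mean(df$prop_mature),
                      sem_prop_mature = sem(df$prop_mature),
                      mean_prop_psd95 = if (length(psd)) mean(psd) else NA_real_,
                      sem_prop_psd95 = if (length(psd) > 1) sem(psd) else NA_real_)
    for (k in 1:8) {
      out[[paste0("mean_class", k)]] <- cls_m[k]
      out[[paste0("sem_class", k)]] <- cls_s[k]
    }
    out
  }))
  rownames(group_means) <- NULL
  groups <- lapply(conds, `[[`, "prop_mature")
  structure(list(cells = cells, group_means = group_means,
                 anova_mature = one_way_anova(groups, metric = "prop_mature")),
            class = "spine_comparison")
}

#' @export
print.spine_comparison <- function(x, ...) {
  cat("Spine maturity by condition (cell as unit of analysis)\n")
  gm <- x$group_means
  for (i in seq_len(nrow(gm))) {
    cat(sprintf("  %s: n = %d cells, mature %.3f +/- %.3f%s\n",
                gm$condition[i], gm$n_cells[i],
                gm$mean_prop_mature[i], gm$sem_prop_mature[i],
                if (!is.na(gm$mean_prop_psd95[i]))
                  sprintf(", PSD-95+ %.3f", gm$mean_prop_psd95[i]) else ""))
  }
  a <- x$anova_mature
  cat(sprintf("  ANOVA on mature proportion: F(%d, %d) = %.4g, p = %.3g\n",
              a$df_between, a$df_within, a$F, a$p))
  invisible(x)
}
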