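## Group-level statistics for drug-versus-control comparisons: Tukey box
## summaries, rank-based two-group comparison, per-condition tallies.

#' Tukey box-plot summary
#'
#' Median and hinges are the type-7 (linear interpolation) quartiles;
#' whiskers extend to the furthest data value strictly less than 1.5 IQR
#' from the corresponding hinge; everything beyond is an outlier.
#'
#' @param values Numeric vector (>= 1 value, finite).
#' @return A [`BoxSummary`][BoxSummary-class].
#' @examples
#' tukeySummary(1:100)
#' @export
tukeySummary <- function(values) {
    if (!length(values)) stop("empty input")
    stopifnot(all(is.finite(values)))
    q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    if (iqr == 0) {
        inWh <- values >= q[1] & values <= q[3]
    } else {
        inWh <- values > q[1] - 1.5 * iqr & values < q[3] + 1.5 * iqr
    }
    wl <- if (any(inWh)) min(values[inWh]) else q[1]
    wh <- if (any(inWh)) max(values[inWh]) else q[3]
    new("BoxSummary", median = q[2], q1 = q[1], q3 = q[3],
        whiskerLow = wl, whiskerHigh = wh,
        outliers = sort(values[!inWh]))
}

#' Two-group rank comparison
#'
#' Two-sided rank-based p-value for a drug-versus-control comparison of
#' unpaired groups. Because condition sizes differ, the operative test is
#' the rank-sum (Mann-Whitney) test: exact for small tie-free samples,
#' normal approximation with tie correction otherwise. Identical pooled
#' values are degenerate: a warning is raised and p = 1 returned.
#'
#' @param drug,control Numeric vectors (nonempty).
#' @return Two-sided p-value.
#' @examples
#' compareGroups(rnorm(20, 1), rnorm(20))
#' @export
compareGroups <- function(drug, control) {
    stopifnot(length(drug) >= 1, length(control) >= 1)
    pooled <- c(drug, control)
    if (length(unique(pooled)) == 1L) {
        warning("degenerate comparison: all pooled values identical",
                call. = FALSE)
        return(1)
    }
    suppressWarnings(
        stats::wilcox.test(drug, control, alternative = "two.sided")$p.value)
}

#' Per-condition tallies
#'
#' @param n Integer vector of per-condition cell counts.
#' @return List with `n_conditions`, `total_cells`, `mean_per_condition`
#'   (integer-rounded) and `mean_exact`.
#' @examples
#' tallyConditions(clinicalConditionCounts()$n)
#' @export
tallyConditions <- function(n) {
    stopifnot(length(n) >= 1, all(n >= 0))
    list(n_conditions = length(n), total_cells = sum(n),
         mean_per_condition = round(sum(n) / length(n)),
         mean_exact = sum(n) / length(n))
}

#' Condition summary table
#'
#' Per-condition box summaries of buoyant mass and mass-normalized MAR plus
#' the tallies of [tallyConditions()].
#'
#' @param conditions Named list; each element a data.frame of per-cell
#'   measurements with columns `mass` (pg), `mar` (pg/h) and `mar_per_mass`
#'   (1/h).
#' @return data.frame with one row per condition (`label`, `n`, and
#'   median/q1/q3 for mass and mass-normalized MAR); the tallies are
#'   attached as `attr(, "tally")`.
#' @examples
#' cells <- data.frame(mass = rnorm(20, 50, 5), mar = rnorm(20, 2),
#'                     mar_per_mass = rnorm(20, 0.04, 0.01))
#' condTab <- conditionTable(list(control = cells, drug = cells))
#' attr(condTab, "tally")$total_cells
#' @export
conditionTable <- function(conditions) {
    stopifnot(length(conditions) >= 1)
    rows <- lapply(names(conditions), function(lbl) {
        d <- conditions[[lbl]]
        bm <- tukeySummary(d$mass)
        bn <- tukeySummary(d$mar_per_mass)
        data.frame(label = lbl, n = nrow(d),
                   mass_median = bm@median, mass_q1 = bm@q1,
                   mass_q3 = bm@q3,
                   mar_per_mass_median = bn@median,
                   mar_per_mass_q1 = bn@q1, mar_per_mass_q3 = bn@q3)
    })
    out <- do.call(rbind, rows)
    attr(out, "tally") <- tallyConditions(out$n)
    out
}

#' Published per-condition cell counts
#'
#' Cell counts of the 13 drug/vehicle conditions measured across six primary
#' brain-lesion specimens (non-tumor brain tissue, newly diagnosed and
#' recurrent glioblastoma, breast and lung metastases, and CNS lymphoma) in
#' the active-loading clinical demonstration panel: 1092 cells in total, a
#' mean of 84 per condition. The caption order of the counts does not carry
#' a reliable condition-to-count mapping, so conditions are identified
#' generically as c01-c13.
#'
#' @return data.frame with columns `condition` and `n`.
#' @examples
#' sum(clinicalConditionCounts()$n)
#' @export
clinicalConditionCounts <- function() {
    data.frame(
        condition = sprintf("c%02d", 1:13),
        n = c(86L, 90L, 63L, 64L, 66L, 83L, 74L, 60L, 47L, 53L, 54L,
              164L, 188L))
}
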