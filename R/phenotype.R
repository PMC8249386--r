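#' Relative proliferation from a flow growth-competition assay
#'
#' The relative proliferation (RP) of fluorescent-protein-positive (FP+,
#' construct-carrying) versus FP- (non-transduced) cells between the day-3
#' baseline and time point t:
#' \deqn{RP = \frac{[N(t)\,FP\%(t)]\,[N(d3)\,(100-FP\%(d3))]}
#'                 {[N(d3)\,FP\%(d3)]\,[N(t)\,(100-FP\%(t))]}}
#' The live-cell counts cancel algebraically, so RP is the odds ratio of
#' the FP+ fraction; the function evaluates both forms and verifies they
#' agree to 1e-12 (relative). FP percentages must lie strictly inside
#' (0, 100), otherwise the odds ratio is undefined.
#'
#' @param n_t,fp_t live count and FP+ percent at time t.
#' @param n_d3,fp_d3 live count and FP+ percent at the day-3 baseline.
#' @return RP (vectorized over inputs).
#' @export
relative_proliferation <- function(n_t, fp_t, n_d3, fp_d3) {
  if (any(fp_t <= 0 | fp_t >= 100 | fp_d3 <= 0 | fp_d3 >= 100))
    stop("undefined odds ratio: FP% must be strictly inside (0, 100)")
  if (any(n_t <= 0 | n_d3 <= 0)) stop("live counts must be positive")
  rp <- (n_t * fp_t) * (n_d3 * (100 - fp_d3)) /
        ((n_d3 * fp_d3) * (n_t * (100 - fp_t)))
  odds <- (fp_t / (100 - fp_t)) / (fp_d3 / (100 - fp_d3))
  stopifnot(all(abs(rp - odds) <= 1e-12 * pmax(1, abs(rp))))
  rp
}

#' Drug-resistance index
#'
#' Resistance index of construct x at dose m:
#' `100 * RP(x, m) / RP(con, m)`, where `con` is the control construct
#' (e.g. a luciferase-targeting guide or a wild-type cDNA).
#'
#' @param rp_x RP of the construct of interest.
#' @param rp_con RP of the control construct at the same dose (must be
#'   positive).
#' @return Resistance index in percent.
#' @export
resistance_index <- function(rp_x, rp_con) {
  if (any(rp_con <= 0)) stop("rp_con must be positive")
  # ratio first, so the control construct is exactly 100
  100 * (rp_x / rp_con)
}

#' Per-row relative proliferation for a flow-count table
#'
#' @param flow data.frame with columns `construct`, `replicate`, `day`,
#'   `live_count`, `fp_percent`, `drug_um`.
#' @param baseline_day baseline time point (default 3).
#' @return `flow` with an added `rp` column (baseline rows have RP 1).
#' @export
proliferation_table <- function(flow, baseline_day = 3) {
  need <- c("construct", "replicate", "day", "live_count", "fp_percent", "drug_um")
  miss <- setdiff(need, names(flow))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  key <- interaction(flow$construct, flow$replicate, flow$drug_um, drop = TRUE)
  flow$rp <- NA_real_
  for (k in levels(key)) {
    rows <- which(key == k)
    base <- rows[flow$day[rows] == baseline_day]
    if (length(base) != 1)
      stop("group ", k, " needs exactly one day-", baseline_day, " baseline row")
    flow$rp[rows] <- relative_proliferation(
      flow$live_count[rows], flow$fp_percent[rows],
      flow$live_count[base], flow$fp_percent[base])
  }
  flow
}

#' Construct x dose resistance-index matrix
#'
#' Summarizes replicates by their mean RP at `day` (default 9), then
#' divides by the control construct's mean RP at the same dose.
#'
#' @param flow a [proliferation_table()] result (or raw flow table, which
#'   is run through it).
#' @param control control construct id.
#' @param day assay day used for the index (default 9).
#' @param baseline_day passed to [proliferation_table()] if `rp` is absent.
#' @return data.frame `construct` x dose columns of resistance indices in
#'   percent (control row exactly 100 at every dose).
#' @export
resistance_table <- function(flow, control, day = 9, baseline_day = 3) {
  if (!"rp" %in% names(flow)) flow <- proliferation_table(flow, baseline_day)
  if (!control %in% flow$construct) stop("control construct '", control, "' absent")
  sel <- flow[flow$day == day, , drop = FALSE]
  if (nrow(sel) == 0) stop("no rows at day ", day)
  agg <- stats::aggregate(rp ~ construct + drug_um, data = sel, FUN = mean)
  doses <- sort(unique(agg$drug_um))
  constructs <- unique(agg$construct)
  out <- data.frame(construct = constructs, stringsAsFactors = FALSE)
  for (m in doses) {
    con_rp <- agg$rp[agg$construct == control & agg$drug_um == m]
    if (length(con_rp) != 1) stop("control RP missing at dose ", m)
    col <- vapply(constructs, function(cc) {
      rp <- agg$rp[agg$construct == cc & agg$drug_um == m]
      if (length(rp) != 1) return(NA_real_)
      resistance_index(rp, con_rp)
    }, numeric(1))
    out[[paste0("dose_", m)]] <- col
  }
  out
}
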