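#' Simulate an Annexin-V flow-cytometry event table
#'
#' Events are drawn from a two-component log-normal mixture: with probability
#' `live_fraction` from the low-intensity (Annexin-V-negative, live)
#' component, otherwise from the high-intensity (Annexin-V-positive,
#' apoptotic) component. `live_mu` and `dead_mu` are the component medians in
#' arbitrary fluorescence units; `sigma` is the common log-scale spread.
#'
#' @param live_fraction true proportion of live cells in `[0, 1]`
#' @param n_events number of events (>= 1)
#' @param live_mu,dead_mu component medians; `dead_mu > live_mu` (apoptotic
#'   cells bind more Annexin-V)
#' @param sigma log-normal `sdlog` of both components
#' @param seed integer seed
#' @param pool_id identifier of the pooled-spheroid sample
#' @return an object of class `"flow_event_table"`: list with `events`,
#'   `pool_id`, `n_events`
#' @export
simulate_events <- function(live_fraction, n_events, live_mu = 100,
                            dead_mu = 1e4, sigma = 0.5, seed = 1L,
                            pool_id = "pool") {
  if (live_fraction < 0 || live_fraction > 1)
    stop("live_fraction must lie in [0, 1]")
  if (n_events < 1) stop("n_events must be >= 1")
  if (dead_mu <= live_mu)
    stop("dead_mu must exceed live_mu (Annexin-V-positive events are brighter)")
  if (sigma <= 0) stop("sigma must be positive")
  events <- with_seed(seed, {
    is_live <- stats::runif(n_events) < live_fraction
    mu <- ifelse(is_live, log(live_mu), log(dead_mu))
    stats::rlnorm(n_events, meanlog = mu, sdlog = sigma)
  })
  structure(list(events = events, pool_id = pool_id,
                 n_events = as.integer(n_events)),
            class = "flow_event_table")
}

#' Default gate: geometric midpoint between the component medians
#' @param live_mu,dead_mu component medians in fluorescence units
#' @return gate threshold intensity
#' @export
default_gate <- function(live_mu = 100, dead_mu = 1e4) sqrt(live_mu * dead_mu)

#' Gate an event table into a live fraction and a viability label
#'
#' The live fraction is the proportion of events with intensity strictly
#' below the gate; the label follows [label_from_viability()].
#'
#' @param table a `"flow_event_table"`
#' @param gate_threshold positive intensity threshold
#' @return an object of class `"viability_result"`: list with
#'   `live_fraction`, `gate_threshold`, `label`, `pool_id`
#' @export
gate_viability <- function(table, gate_threshold = default_gate()) {
  stopifnot(inherits(table, "flow_event_table"))
  if (length(table$events) == 0)
    stop("empty event table: viability undefined")
  if (gate_threshold <= 0) stop("gate threshold must be positive")
  lf <- mean(table$events < gate_threshold)
  structure(list(live_fraction = lf, gate_threshold = gate_threshold,
                 label = label_from_viability(lf), pool_id = table$pool_id),
            class = "viability_result")
}

#' Map a live fraction to the three-category viability label
#'
#' The categories follow the published definitions: `unaffected` above 80%
#' viability (exclusive), `mildly_affected` between 40% and 60% (closed
#' interval), `affected` below 40% (exclusive). Fractions in the uncovered
#' band `(0.60, 0.80]` map to `"unlabeled"` and are excluded from training.
#'
#' @param live_fraction numeric vector in `[0, 1]`
#' @return character vector of labels, same length
#' @examples
#' label_from_viability(c(0.85, 0.5, 0.3, 0.7))
#' @export
label_from_viability <- function(live_fraction) {
  if (any(is.na(live_fraction)) || any(live_fraction < 0 | live_fraction > 1))
    stop("live_fraction must lie in [0, 1]")
  ifelse(live_fraction > 0.80, "unaffected",
    ifelse(live_fraction >= 0.40 & live_fraction <= 0.60, "mildly_affected",
      ifelse(live_fraction < 0.40, "affected", "unlabeled")))
}

#' Write / read event tables as CSV
#'
#' One row per event, columns `pool_id`, `annexin_intensity`. Several tables
#' can share one file.
#'
#' @param tables a `"flow_event_table"` or list of them
#' @param path CSV path
#' @export
write_flow_csv <- function(tables, path) {
  if (inherits(tables, "flow_event_table")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, function(t)
    data.frame(pool_id = t$pool_id, annexin_intensity = t$events)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_csv
#' @export
read_flow_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pool_id", "annexin_intensity") %in% names(df)))
    stop("flow CSV must have columns pool_id, annexin_intensity")
  lapply(split(df, df$pool_id), function(d)
    structure(list(events = d$annexin_intensity, pool_id = d$pool_id[1],
                   n_events = nrow(d)), class = "flow_event_table"))
}

#' @export
print.viability_result <- function(x, ...) {
  cat(sprintf("<viability_result %s>: live fraction %.3f (gate %.1f) -> %s\n",
              x$pool_id, x$live_fraction, x$gate_threshold, x$label))
  invisible(x)
}
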