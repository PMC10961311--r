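#' Truncated coefficient of variation
#'
#' CV (standard deviation over mean, population convention) computed on the
#' part of a biomass series before its terminal collapse: samples from the
#' start up to, but excluding, the final run of values below the extinction
#' threshold. A series that never permanently falls below the threshold is
#' used whole; a series entirely below it has no defined CV and returns NA.
#'
#' @param series Numeric biomass series (g/m2).
#' @param threshold Extinction threshold, default 1e-6 g/m2.
#' @return Nonnegative scalar CV, or NA if the series never rises above the
#'   threshold.
#' @export
truncated_cv <- function(series, threshold = 1e-6) {
  stopifnot(length(series) > 0)
  below <- series < threshold
  if (all(below)) return(NA_real_)
  # index of the last sample of the pre-collapse prefix
  last_ok <- max(which(!below))
  prefix <- series[seq_len(last_ok)]
  m <- mean(prefix)
  if (m == 0) return(NA_real_)
  sqrt(mean((prefix - m)^2)) / m
}

#' Per-species CVs normalized to the offshore phytoplankton series
#'
#' Computes each species' truncated CV over the trajectory and divides it by
#' the CV of the offshore phytoplankton series over the same window, giving
#' a dimensionless sensitivity of each population's fluctuations to the
#' fluctuations of the subsidy itself. Results carry the guild labels for
#' distributional summaries.
#'
#' @param trajectory An `atn_trajectory`.
#' @param op_series Numeric offshore-phytoplankton biomass series covering
#'   the same window (e.g. the scaled daily samples, or the forcing
#'   evaluated on the trajectory's times).
#' @param guilds Tibble `node_id, guild` from [assign_guilds()].
#' @param threshold Extinction threshold for truncation.
#' @return A `cv_report` tibble: `node_id, guild, cv_raw, cv_norm`, one row
#'   per dynamic node.
#' @export
normalized_cv_report <- function(trajectory, op_series, guilds,
                                 threshold = 1e-6) {
  stopifnot(inherits(trajectory, "atn_trajectory"))
  cv_op <- truncated_cv(op_series, threshold)
  if (is.na(cv_op) || cv_op == 0) {
    stop("offshore phytoplankton CV is zero or undefined; ",
         "cannot normalize", call. = FALSE)
  }
  cv_raw <- apply(trajectory$biomass, 2, truncated_cv, threshold = threshold)
  out <- tibble::tibble(node_id = colnames(trajectory$biomass),
                        cv_raw = unname(cv_raw),
                        cv_norm = unname(cv_raw) / cv_op) |>
    dplyr::left_join(guilds, by = "node_id") |>
    dplyr::select("node_id", "guild", "cv_raw", "cv_norm")
  class(out) <- c("cv_report", class(out))
  attr(out, "cv_op") <- cv_op
  out
}

#' Biomass-range summary for node groups
#'
#' For each named group of nodes, the minimum and maximum over a time window
#' of the group's summed biomass — the vertical extent of its trajectory
#' envelope.
#'
#' @param trajectory An `atn_trajectory`.
#' @param groups Named list of node-id vectors (e.g. producers, algae,
#'   filter feeders, consumers).
#' @param window Optional `c(t0, t1)` in hours; default the whole
#'   trajectory.
#' @return Tibble `group, min_g_m2, max_g_m2`.
#' @export
biomass_range_summary <- function(trajectory, groups, window = NULL) {
  stopifnot(inherits(trajectory, "atn_trajectory"), length(groups) > 0)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named list", call. = FALSE)
  }
  keep <- rep(TRUE, length(trajectory$times))
  if (!is.null(window)) {
    keep <- trajectory$times >= window[1] & trajectory$times <= window[2]
    if (!any(keep)) stop("empty window", call. = FALSE)
  }
  purrr::imap_dfr(groups, function(ids, nm) {
    if (length(ids) == 0) stop("empty group: ", nm, call. = FALSE)
    miss <- setdiff(ids, colnames(trajectory$biomass))
    if (length(miss) > 0) {
      stop("group '", nm, "' names unknown node(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    total <- rowSums(trajectory$biomass[keep, ids, drop = FALSE])
    tibble::tibble(group = nm, min_g_m2 = min(total), max_g_m2 = max(total))
  })
}

#' Extirpation status table across years and mixing rates
#'
#' Reshapes a [scan_mixing()] result into the year-by-mixing-rate status
#' table for one focal species: one row per year with its peak offshore
#' phytoplankton abundance and an `"e"` in each mixing-rate column where the
#' focal species was extirpated (blank where it survived).
#'
#' @param scan_result Tibble from [scan_mixing()].
#' @param focal Node id of the focal species.
#' @return Tibble `year, peak_op` plus one `k<rate>` column per mixing rate,
#'   sorted by decreasing rate.
#' @export
extirpation_table <- function(scan_result, focal) {
  stopifnot(is.character(focal), length(focal) == 1)
  if (nrow(scan_result) == 0) {
    return(tibble::tibble(year = character(), peak_op = numeric()))
  }
  known <- unique(unlist(c(scan_result$extirpated, focal)))
  status <- scan_result |>
    dplyr::mutate(status = purrr::map_chr(
      .data$extirpated, ~ if (focal %in% .x) "e" else ""
    )) |>
    dplyr::select("year", "peak_op", "k_mixing", "status")
  ks <- sort(unique(status$k_mixing), decreasing = TRUE)
  status |>
    dplyr::mutate(k_mixing = factor(paste0("k", .data$k_mixing),
                                    levels = paste0("k", ks))) |>
    dplyr::arrange(.data$year, .data$k_mixing) |>
    tidyr::pivot_wider(names_from = "k_mixing", values_from = "status",
                       values_fill = "")
}
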