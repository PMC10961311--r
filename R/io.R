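# CSV readers/writers for the package's exchange schemas. All files are
# plain UTF-8 CSV; ids are opaque strings.

#' Read a species table
#'
#' Schema: `node_id,name,body_mass_g,role[,guild_override
#' ][,initial_biomass_g_m2]` with role in producer/consumer/phytoplankton.
#'
#' @param path CSV file path.
#' @return Tibble of validated species records.
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  req <- c("node_id", "name", "body_mass_g", "role")
  if (!all(req %in% names(df))) {
    stop("species table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  mass <- suppressWarnings(as.numeric(df$body_mass_g))
  bad <- which(is.na(mass) & !is.na(df$body_mass_g))
  if (length(bad) > 0) {
    stop("unparseable body_mass_g at data row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df$body_mass_g <- mass
  if ("initial_biomass_g_m2" %in% names(df)) {
    df$initial_biomass_g_m2 <- as.numeric(df$initial_biomass_g_m2)
  }
  dup <- unique(df$node_id[duplicated(df$node_id)])
  if (length(dup) > 0) {
    stop("duplicated node_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a trophic edge list
#'
#' Schema: `consumer_id,resource_id`, one feeding link per row.
#'
#' @param path CSV file path.
#' @return Tibble of link records.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!all(c("consumer_id", "resource_id") %in% names(df))) {
    stop("edge list must have columns consumer_id, resource_id",
         call. = FALSE)
  }
  df
}

#' Read a daily chlorophyll series
#'
#' Schema: `date,chloro_g_m3`, ISO-8601 dates, one row per sampled day.
#'
#' @param path CSV file path.
#' @return Validated tibble (strictly increasing dates, nonnegative
#'   densities).
#' @export
read_chloro <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(date = "D",
                                                chloro_g_m3 = "d"))
  validate_chloro(df)
}

#' Write a trajectory to CSV
#'
#' One row per output time: `t_hours` plus one column per dynamic node id.
#' Extirpation annotations go to a side file `<path>.extirpations.csv` when
#' any occurred.
#'
#' @param trajectory An `atn_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "atn_trajectory"))
  df <- tibble::as_tibble(as.data.frame(trajectory$biomass))
  df <- dplyr::bind_cols(tibble::tibble(t_hours = trajectory$times), df)
  readr::write_csv(df, path)
  if (nrow(trajectory$extirpations) > 0) {
    readr::write_csv(trajectory$extirpations,
                     paste0(path, ".extirpations.csv"))
  }
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV path.
#' @param phase,k_mixing Metadata to attach (not stored in the CSV).
#' @return An `atn_trajectory` (extirpations reloaded from the side file if
#'   present).
#' @export
read_trajectory <- function(path, phase = "experimental", k_mixing = NA) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (names(df)[1] != "t_hours") {
    stop("not a trajectory file (first column must be t_hours)",
         call. = FALSE)
  }
  ext_path <- paste0(path, ".extirpations.csv")
  ext <- if (file.exists(ext_path)) {
    readr::read_csv(ext_path, show_col_types = FALSE,
                    col_types = readr::cols(node_id = "c", t_hours = "d"))
  } else {
    tibble::tibble(node_id = character(), t_hours = numeric())
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  new_trajectory(df$t_hours, mat, ext, phase, k_mixing)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-identically: the
#' configuration snapshot, md5 digests of the input files, the package
#' version, the seed, and a timestamp. YAML, written alongside the outputs.
#'
#' @param path Manifest output path.
#' @param config An `atn_config` (or any list) snapshot.
#' @param inputs Character vector of input file paths to digest.
#' @param seed Integer seed used for the run (or NULL).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, inputs = character(),
                               seed = NULL) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  manifest <- list(
    package = "atnsubsidy",
    version = as.character(utils::packageVersion("atnsubsidy")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    input_digests = digests,
    config = unclass(config)
  )
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Export a forcing function on a grid
#'
#' @param fn An `atn_forcing`.
#' @param path Output CSV (`t_hours,B_op_g_m2`).
#' @param by Grid step in hours.
#' @return `path`, invisibly.
#' @export
write_forcing_grid <- function(fn, path, by = 24) {
  t <- seq(fn$t_min, fn$t_max, by = by)
  readr::write_csv(tibble::tibble(t_hours = t,
                                  B_op_g_m2 = evaluate_forcing(fn, t)),
                   path)
  invisible(path)
}
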