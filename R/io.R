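# Readers and writers for the pipeline's plain-text formats: individual
# record tables and EA site tables as CSV, rasters as ESRI ASCII grids
# (see read_raster/write_raster). Travel-time categories are serialized as
# the literal tokens LT1H / H1TO2 / GT2H, with empty cells for item
# nonresponse.

records_schema <- function() {
  c("ea_id", "stratum", "sex", "age_group", "hiv_positive", "on_art",
    "traveltime_category", "design_weight")
}

#' Read and write survey record tables
#'
#' One row per individual; replicate weights as numbered columns
#' `rw001`, `rw002`, .... `write_records` never writes the internal
#' true-coordinate columns. `read_records` validates the schema and the
#' record-level invariants (categories are valid tokens, `on_art` implies
#' `hiv_positive`, travel-time answered only if on ART, positive design
#' weights) and reports offending columns or rows.
#'
#' @param records Record table.
#' @param path CSV path.
#' @return `write_records` returns `path` invisibly; `read_records` the
#'   validated data.frame.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(records_schema(), names(rec))
  if (length(missing_cols) > 0)
    stop("I/O error: records file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  rec$hiv_positive <- as.logical(rec$hiv_positive)
  rec$on_art <- as.logical(rec$on_art)
  bad_cat <- which(!is.na(rec$traveltime_category) &
                     !rec$traveltime_category %in% traveltime_levels())
  if (length(bad_cat) > 0)
    stop("I/O error: invalid traveltime_category at row(s) ",
         paste(utils::head(bad_cat, 5), collapse = ", "),
         " (expected LT1H, H1TO2, GT2H or empty)", call. = FALSE)
  bad_str <- which(!rec$stratum %in% c("urban", "rural"))
  if (length(bad_str) > 0)
    stop("I/O error: invalid stratum at row(s) ",
         paste(utils::head(bad_str, 5), collapse = ", "), call. = FALSE)
  if (any(rec$design_weight <= 0 | is.na(rec$design_weight)))
    stop("I/O error: design_weight must be positive", call. = FALSE)
  if (any(rec$on_art & !rec$hiv_positive))
    stop("I/O error: on_art records must be hiv_positive", call. = FALSE)
  if (any(!is.na(rec$traveltime_category) & !rec$on_art))
    stop("I/O error: traveltime_category present for off-ART record(s)",
         call. = FALSE)
  rec
}

#' Read and write EA site tables
#'
#' Geomasked site coordinates only (`ea_id`, `x_km`, `y_km`, `stratum`);
#' the generator's true coordinates are deliberately dropped.
#'
#' @param sites Site table.
#' @param path CSV path.
#' @export
write_sites <- function(sites, path) {
  utils::write.csv(sites[, c("ea_id", "x_km", "y_km", "stratum")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ea_id", "x_km", "y_km", "stratum")
  miss <- setdiff(need, names(s))
  if (length(miss) > 0)
    stop("I/O error: sites file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  s
}

#' Cluster-level prevalence points
#'
#' Aggregates individual records to EA-level weighted HIV prevalence and
#' joins the (geomasked) site coordinates — the input of the kriging stage.
#'
#' @param records Record table.
#' @param sites Site table with `ea_id`, `x_km`, `y_km`.
#' @return Data.frame `x_km`, `y_km`, `z` (prevalence), `n`.
#' @export
cluster_prevalence <- function(records, sites) {
  agg <- do.call(rbind, lapply(split(records, records$ea_id), function(d)
    data.frame(ea_id = d$ea_id[1],
               z = sum(d$design_weight * d$hiv_positive) / sum(d$design_weight),
               n = nrow(d), stringsAsFactors = FALSE)))
  m <- merge(sites[, c("ea_id", "x_km", "y_km")], agg, by = "ea_id")
  m[order(m$ea_id), c("x_km", "y_km", "z", "n")]
}
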