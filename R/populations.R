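# Population metadata: id, geographic coordinates, sample size.

#' Construct and validate a population table
#'
#' @param id character vector of unique population identifiers.
#' @param latitude degrees in \[-90, 90\].
#' @param longitude degrees in \[-180, 180\].
#' @param n_individuals positive integer sample sizes.
#' @return data.frame with the four columns above.
#' @export
population_table <- function(id, latitude, longitude = 0,
                             n_individuals = 25L) {
  df <- data.frame(id = as.character(id),
                   latitude = as.numeric(latitude),
                   longitude = as.numeric(rep_len(longitude, length(id))),
                   n_individuals = as.integer(rep_len(n_individuals,
                                                      length(id))),
                   stringsAsFactors = FALSE)
  validate_populations(df)
}

validate_populations <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("id", "latitude", "longitude", "n_individuals")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("population table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stopf("duplicated population id '%s'",
                                  df$id[anyDuplicated(df$id)])
  if (any(abs(df$latitude) > 90)) stopf("latitude outside [-90, 90]")
  if (any(abs(df$longitude) > 180)) stopf("longitude outside [-180, 180]")
  if (any(df$n_individuals < 1)) stopf("n_individuals must be positive")
  df
}

#' Read / write population metadata TSV
#'
#' Tab-separated with header `id  latitude  longitude  n_individuals`.
#' @param path file path.
#' @param populations data.frame per [population_table()].
#' @export
read_population_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_populations(df)
}

#' @rdname read_population_table
#' @export
write_population_table <- function(populations, path) {
  validate_populations(populations)
  utils::write.table(populations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
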