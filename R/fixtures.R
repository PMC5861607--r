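#' Published validation tables
#'
#' The two per-dog validation tables from the study this package implements,
#' packaged as fixtures: `table1` gives the 13 healthy dogs of the step-count
#' experiment (video-annotated vs algorithm step counts, one walk each);
#' `table2` gives the 10 osteoarthritic dogs of the distance experiment with
#' per-walk GPS and algorithm distance estimates in metres (15 walks in all;
#' list-columns `gps_dists_m`, `algo_dists_m` hold one value per walk).
#'
#' @return A list with elements `table1` and `table2`, both tibbles.
#' @examples
#' fx <- study_fixtures()
#' sum(fx$table1$steps_video)   # 4695 annotated steps
#' @export
study_fixtures <- function() {
  t1 <- readr::read_csv(
    system.file("extdata", "table1_step_counts.csv", package = "caninestep",
                mustWork = TRUE),
    col_types = "cddcdcii", progress = FALSE)
  walks <- table2_walks()
  t2 <- walks |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n_walks = dplyr::n(),
      weight_kg = dplyr::first(.data$weight_kg),
      breed = dplyr::first(.data$breed),
      sex = dplyr::first(.data$sex),
      gps_dists_m = list(.data$gps_dist_m),
      algo_dists_m = list(.data$algo_dist_m),
      .groups = "drop") |>
    dplyr::arrange(match(.data$id, unique(walks$id)))
  list(table1 = t1, table2 = t2)
}

#' @return `table2_walks()` returns the distance table in long form, one row
#'   per walk with columns `id`, `walk`, `gps_dist_m`, `algo_dist_m`.
#' @rdname study_fixtures
#' @export
table2_walks <- function() {
  readr::read_csv(
    system.file("extdata", "table2_walk_distances.csv",
                package = "caninestep", mustWork = TRUE),
    col_types = "cidccdd", progress = FALSE)
}
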