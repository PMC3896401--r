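#' Read simulation parameters from a config file
#'
#' Reads a YAML or JSON file whose top-level keys mirror the [sim_params()]
#' arguments field for field (unknown keys are an error). `overrides` (e.g.
#' parsed CLI flags) take precedence over file values.
#'
#' @param path Path to a `.yaml` / `.yml` / `.json` file, or `NULL` to build
#'   purely from `overrides`.
#' @param overrides Named list of [sim_params()] arguments.
#' @return A validated [sim_params()] object.
#' @export
read_sim_config <- function(path = NULL, overrides = list()) {
  args <- list()
  if (!is.null(path)) {
    stop_unless(file.exists(path), paste0("config file not found: ", path))
    args <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    stop_unless(is.list(args), "config file must hold a mapping of parameters")
  }
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  unknown <- setdiff(names(args), names(formals(sim_params)))
  if (length(unknown))
    stop("unknown parameter(s) in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_params, args)
}

#' Write a run's frozen records to a delimited file
#'
#' Writes the long-format table of [frozen_records_table()] as tab-separated
#' text with a header.
#'
#' @param run A `sim_run` object.
#' @param path Output file path.
#' @param replicate Replicate label for the first column.
#' @return `path`, invisibly.
#' @export
write_frozen_records <- function(run, path, replicate = 1L) {
  tab <- frozen_records_table(run, replicate = replicate)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read frozen records written by [write_frozen_records()]
#'
#' @param path Path to the tab-separated frozen-record table.
#' @return Data.frame with columns `replicate`, `column_index`,
#'   `generation_recorded`, `row_index`, `frequency`.
#' @export
read_frozen_records <- function(path) {
  tab <- utils::read.delim(path)
  need <- c("replicate", "column_index", "generation_recorded", "row_index",
            "frequency")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("frozen-record table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab
}

#' Plot a run's frozen-record frequencies as a heatmap
#'
#' Renders the lattice's frozen-record allele-A frequencies with rows on the
#' vertical axis and columns (the expansion direction) on the horizontal axis:
#' green for frequency 0, red for 1, yellow for intermediate, black for
#' columns without a record.
#'
#' @param run A `sim_run` object.
#' @param ... Passed on to [graphics::image()].
#' @return The run, invisibly.
#' @export
plot_frozen_records <- function(run, ...) {
  stopifnot(inherits(run, "sim_run"))
  z <- t(run$freq)
  pal <- grDevices::colorRampPalette(c("green3", "yellow", "red"))(101)
  graphics::image(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                  z = z, zlim = c(0, 1), col = pal,
                  xlab = "lattice column (expansion direction)",
                  ylab = "lattice row", useRaster = TRUE, ...)
  na_cols <- which(apply(is.na(run$freq), 2, all))
  if (length(na_cols))
    graphics::rect(na_cols - 0.5, 0.5, na_cols + 0.5, nrow(run$freq) + 0.5,
                   col = "black", border = NA)
  invisible(run)
}
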