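#' Read and write COLVAR-style CV time series
#'
#' PLUMED-style whitespace-delimited files with a `#! FIELDS time cv ...`
#' header line. `read_colvar()` returns every field as a column;
#' `write_colvar()` writes a data frame the same way.
#'
#' @param path file path.
#' @return `read_colvar()`: a tibble with the file's fields as columns.
#' @export
read_colvar <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^#!\\s*FIELDS", first)) {
    fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", first), "\\s+")[[1]]
    df <- readr::read_table(path, col_names = fields, comment = "#",
                            col_types = readr::cols(.default = "d"))
  } else {
    df <- readr::read_table(path, col_names = c("time", "cv"), comment = "#",
                            col_types = readr::cols(.default = "d"))
  }
  tibble::as_tibble(df)
}

#' @rdname read_colvar
#' @param df data frame of numeric columns; the first should be time.
#' @export
write_colvar <- function(df, path) {
  header <- paste("#! FIELDS", paste(names(df), collapse = " "))
  body <- do.call(paste, c(unname(lapply(df, format, digits = 10,
                                         scientific = FALSE, trim = TRUE)),
                           sep = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a first-passage ensemble as CSV
#'
#' Scalar per-walker columns only (`walker`, `fpt_ns`, `n_resets`,
#' `censored`); recorded CV series are not serialized.
#'
#' @param ensemble an `fpt_ensemble`.
#' @param path output file.
#' @export
write_fpt_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "fpt_ensemble"))
  cols <- intersect(c("walker", "fpt_ns", "n_steps", "n_resets", "censored"),
                    names(ensemble))
  readr::write_csv(tibble::as_tibble(ensemble)[cols], path)
  invisible(path)
}

#' Read a simulation config block
#'
#' Accepts JSON or simple `key = value` lines. Used by the command-line
#' interface; programmatic use should call the constructors directly.
#'
#' @param path config file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  joined <- paste(txt, collapse = "\n")
  if (grepl("^\\s*\\{", joined)) return(jsonlite::fromJSON(joined))
  txt <- txt[!grepl("^\\s*(#|$)", txt)]
  kv <- strsplit(txt, "\\s*=\\s*")
  vals <- lapply(kv, function(p) {
    v <- utils::type.convert(p[2], as.is = TRUE)
    v
  })
  stats::setNames(vals, vapply(kv, `[`, "", 1))
}

#' Build a surface from a parsed config block
#'
#' The block must contain a `surface` name (`mfe`, `double_well` or
#' `linear`); remaining recognized keys are passed to the matching
#' constructor.
#'
#' @param cfg a named list, e.g. from [read_config()].
#' @return A `potential_surface`.
#' @export
surface_from_config <- function(cfg) {
  name <- cfg$surface %||% stop("config block has no `surface` entry")
  ctor <- switch(name,
                 mfe = mfe_surface,
                 double_well = double_well_surface,
                 linear = linear_surface,
                 stop("unknown surface name: '", name, "'"))
  args <- cfg[intersect(names(cfg), names(formals(ctor)))]
  do.call(ctor, args)
}

#' Write a screening grid as CSV plus a JSON summary
#'
#' @param grid an `isr_prediction` from [screen_protocols()].
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @export
write_prediction <- function(grid, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(grid, "isr_prediction"))
  if (!is.null(csv_path))
    readr::write_csv(tibble::as_tibble(grid), csv_path)
  if (!is.null(json_path)) {
    best <- attr(grid, "argmax")
    jsonlite::write_json(list(
      baseline_mfpt_ns = attr(grid, "baseline_mfpt_ns"),
      best = as.list(best)), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(grid)
}
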