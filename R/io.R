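#' Read a delimited table with validation
#'
#' Reads a `.csv` or `.tsv` file (delimiter inferred from the extension),
#' checks that the required columns are present, and reports non-numeric
#' cells in columns expected to be numeric.
#'
#' @param path File path ending in `.csv` or `.tsv`.
#' @param required_columns Character vector of column names that must be
#'   present.
#' @param numeric_columns Columns that must parse as numeric; defaults to
#'   all required columns except `sample_id`.
#' @return A data frame.
#' @export
load_tabular <- function(path, required_columns = character(),
                         numeric_columns = setdiff(required_columns,
                                                   "sample_id")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t"
         else if (grepl("\\.csv$", path, ignore.case = TRUE)) ","
         else stop("cannot infer delimiter: path must end in .csv or .tsv",
                   call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required_columns, names(tab))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in intersect(numeric_columns, names(tab))) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v))
      if (length(bad) > 0)
        stop("non-numeric value in column '", col, "', row ", bad[1L],
             ": '", v[bad[1L]], "'", call. = FALSE)
      tab[[col]] <- coerced
    }
  }
  tab
}

#' Serialize a run configuration to YAML
#'
#' Writes (or renders) the architecture/training configuration block used
#' by the command-line interface, with keys `kind`, `n`, `input_dim`,
#' `dropout`, `epochs`, `num_batches`, `learning_rate`, `seed`.
#'
#' @param kind Architecture rule.
#' @param n Sample size the architecture is scaled to.
#' @param input_dim Number of covariates.
#' @param control A [relu_control()].
#' @param path Optional file path; if `NULL` the YAML text is returned.
#' @return The YAML string, invisibly if written to `path`.
#' @export
write_run_config <- function(kind, n, input_dim, control = relu_control(),
                             path = NULL) {
  cfg <- list(kind = kind, n = as.integer(n),
              input_dim = as.integer(input_dim),
              dropout = control$dropout, epochs = control$epochs,
              num_batches = control$num_batches,
              learning_rate = control$learning_rate %||% "auto",
              seed = control$seed)
  txt <- yaml::as.yaml(cfg)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a YAML run configuration
#'
#' Inverse of [write_run_config()]: returns the architecture spec and
#' control object encoded in a YAML block.
#'
#' @param path Path to a YAML file.
#' @return A list with `kind`, `n`, `spec` (a [relu_spec()]) and `control`
#'   (a [relu_control()]).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("kind", "n", "input_dim")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0)
    stop("config missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lr <- cfg$learning_rate
  if (identical(lr, "auto")) lr <- NULL
  control <- relu_control(
    epochs = cfg$epochs %||% 200L,
    num_batches = cfg$num_batches %||% 20L,
    learning_rate = lr,
    dropout = cfg$dropout %||% 0.05,
    seed = cfg$seed %||% 1L
  )
  list(kind = cfg$kind, n = cfg$n,
       spec = build_architecture(cfg$kind, cfg$n, cfg$input_dim,
                                 control$dropout),
       control = control)
}
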