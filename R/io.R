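# Delimited-text and JSON artifact I/O. Every tabular artifact is CSV with
# an explicit header, preceded by '#key=value' provenance comment lines
# (package version, config hash, seed) so that any output can be traced back
# to the configuration that produced it.

pkg_version <- function() as.character(utils::packageVersion("ashca"))

#' Hash of a parameter configuration
#'
#' MD5 digest of the serialized free + fixed parameter values; changes
#' whenever any parameter changes.
#'
#' @param params An `ash_params`.
#' @return Character scalar (32 hex digits).
#' @export
config_hash <- function(params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(format(c(params$free, params$fixed), digits = 17),
                   collapse = ","), tmp)
  unname(tools::md5sum(tmp))
}

write_stamped_csv <- function(df, path, meta = list()) {
  meta <- c(list(package = "ashca", version = pkg_version()), meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("#%s=%s", k, meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_stamped_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"), check.names = FALSE),
    error = function(e) stop("malformed CSV in ", path, ": ", conditionMessage(e)))
  list(data = df, meta = meta)
}

#' Write a simulated trace to CSV
#'
#' Columns: time, the 10 states, stimulus, percent FRET, and the seven
#' component fluxes; provenance (package version, configuration hash,
#' divergence flag) in leading comment lines.
#'
#' @param trace An `ash_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  p <- attr(trace, "params")
  write_stamped_csv(as.data.frame(trace), path,
                    meta = list(config = config_hash(p),
                                diverged = isTRUE(attr(trace, "diverged"))))
}

#' Read a trace written by [write_trace()]
#' @param path File path.
#' @return data.frame with a `diverged` attribute.
#' @export
read_trace <- function(path) {
  x <- read_stamped_csv(path)
  structure(x$data, diverged = identical(x$meta$diverged, "TRUE"))
}

#' Write a cohort FRET dataset to CSV
#'
#' @param dataset An `ash_dataset` (columns time, mean, sd, cohort).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  meta <- list()
  if (!is.null(attr(dataset, "seed"))) meta$seed <- attr(dataset, "seed")
  if (!is.null(attr(dataset, "n_replicates"))) {
    meta$n_replicates <- attr(dataset, "n_replicates")
  }
  write_stamped_csv(as.data.frame(dataset), path, meta)
}

#' Read a cohort FRET dataset
#'
#' Validates the schema (`time`, `mean`, `sd` columns; strictly increasing
#' grid; strictly positive sd — required by the standardized-residual
#' objective).
#'
#' @param path CSV written by [write_dataset()] or hand-prepared with the
#'   same header.
#' @return An `ash_dataset`.
#' @export
read_dataset <- function(path) {
  x <- read_stamped_csv(path)
  df <- x$data
  need <- c("time", "mean", "sd")
  if (!all(need %in% names(df))) {
    stop("dataset must have columns time, mean, sd (got: ",
         paste(names(df), collapse = ", "), ")")
  }
  if (any(diff(df$time) <= 0)) stop("dataset time grid must be strictly increasing")
  if (any(df$sd <= 0)) stop("dataset sd must be > 0 at every time point")
  if (is.null(df$cohort)) df$cohort <- "unknown"
  n_rep <- if (!is.null(x$meta$n_replicates)) as.integer(x$meta$n_replicates) else NA_integer_
  structure(df, class = c("ash_dataset", "data.frame"),
            n_replicates = n_rep,
            seed = if (!is.null(x$meta$seed)) as.integer(x$meta$seed) else NA_integer_)
}

#' Write a fit result as JSON
#'
#' @param fit An `ash_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(package = "ashca", version = pkg_version(),
              config = config_hash(fit$params), seed = fit$seed,
              free = fit$free,
              estimates = as.list(fit$params$free),
              rss = fit$rss,
              cov_diag = as.list(fit$cov_diag),
              converged = fit$converged, n_eval = fit$n_eval)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write transient features as a flat JSON record
#' @param features An `ash_features`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_json <- function(features, path) {
  jsonlite::write_json(c(list(package = "ashca", version = pkg_version()),
                         unclass(features)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
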