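#' Read a numeric matrix from delimited text
#'
#' Supports tab- and comma-separated numeric tables and PLINK-style additive
#' genotype text (a header row of variant identifiers followed by one row of
#' 0/1/2 codes per subject; missing codes are imputed to the column mean of
#' the observed codes). Subjects are rows; use `transpose = TRUE` for
#' feature-major files.
#'
#' @param path file path.
#' @param format `"tsv"`, `"csv"`, or `"plink_additive"`.
#' @param header does the file have a header row? (forced `TRUE` for
#'   `plink_additive`).
#' @param transpose transpose after reading.
#' @return numeric matrix, with column names when a header is present.
#' @export
read_matrix <- function(path, format = c("tsv", "csv", "plink_additive"),
                        header = FALSE, transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- switch(format, tsv = "\t", csv = ",", plink_additive = "")
  nf <- utils::count.fields(path, sep = sep, blank.lines.skip = TRUE)
  if (length(nf) == 0L) stop("empty file: ", path)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged table: row ", bad, " has ", nf[bad], " fields, expected ",
         nf[1])
  }
  if (format == "plink_additive") header <- TRUE
  tab <- utils::read.table(path, sep = sep, header = header,
                           stringsAsFactors = FALSE, check.names = FALSE)
  numeric_cols <- vapply(tab, is.numeric, logical(1))
  logical_na <- vapply(tab, function(col) is.logical(col) && all(is.na(col)),
                       logical(1))
  if (!all(numeric_cols | logical_na)) {
    stop("non-numeric entries in column(s): ",
         paste(which(!(numeric_cols | logical_na)), collapse = ", "))
  }
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  if (format == "plink_additive") {
    codes <- m[!is.na(m)]
    if (!all(codes %in% c(0, 1, 2))) {
      stop("plink_additive codes must be 0, 1, 2 or NA")
    }
    n_missing <- sum(is.na(m))
    if (n_missing > 0L) {
      for (j in seq_len(ncol(m))) {
        miss <- is.na(m[, j])
        if (any(miss)) m[miss, j] <- mean(m[!miss, j])
      }
      message("imputed ", n_missing, " missing genotype code(s) to column ",
              "means")
    }
  } else if (anyNA(m)) {
    stop("missing values in ", format, " input")
  }
  if (transpose) m <- t(m)
  m
}

#' Serialize a result object to disk
#'
#' Writes an `"adamant"` result as JSON (scalar fields, the resolved
#' configuration, the grid summary, a tabulated histogram of the selected
#' penalties, and provenance: package version, seed, timestamp), or a
#' `"rejection_summary"` / `"cv_curve"` as a TSV table. The full statistic
#' cross-table of an `"adamant"` fit is written only on request, to
#' `<path>.tcross.tsv`.
#'
#' @param result an `"adamant"`, `"rejection_summary"`, or `"cv_curve"`
#'   object.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @param cross also dump the statistic cross-table (requires a fit made
#'   with `keep_cross = TRUE`).
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = c("json", "tsv"),
                         cross = FALSE) {
  format <- match.arg(format)
  ver <- as.character(utils::packageVersion("adamant"))
  if (inherits(result, "adamant")) {
    if (format != "json") stop("adamant results are written as JSON")
    lh <- table(result$lambda_hat)
    out <- list(
      package = "adamant", version = ver,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = result$seed,
      config = list(method = result$method, cv = result$cv, B = result$B,
                    M = result$grid$M, tau = result$grid$tau_quantile,
                    lambda_max = result$grid$lambda_max, n = result$n,
                    p = result$p, clip_weights = result$clip_weights,
                    exclude_self = result$exclude_self),
      grid = list(lambda_min = result$grid$lambda_min,
                  lambda_max = result$grid$lambda_max,
                  tau = result$grid$tau, ell_min = result$grid$ell_min,
                  M = result$grid$M, n_valid = sum(result$grid$valid)),
      p_value = result$p.value, statistic = result$statistic,
      lambda_hat = result$lambda_hat[1], inner_p = result$inner_p[1],
      lambda_hat_histogram = list(value = as.numeric(names(lh)),
                                  count = as.integer(lh))
    )
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    if (cross) {
      if (is.null(result$T_cross)) {
        stop("no cross-table stored; refit with keep_cross = TRUE")
      }
      utils::write.table(result$T_cross, paste0(path, ".tcross.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    }
  } else if (inherits(result, "rejection_summary")) {
    cfg <- result$config
    row <- data.frame(
      covariance = cfg$covariance, p = cfg$p, tau = as.character(cfg$tau),
      response = cfg$response, sigma = cfg$sigma, method = cfg$method,
      cv = cfg$cv, rate = result$rate, mc_se = result$mc_se,
      S = result$S_effective, B = cfg$B, M = cfg$M, alpha = result$alpha,
      lambda_hat_mean = result$lambda_hat_mean, seed = cfg$seed,
      version = ver
    )
    if (format == "tsv") {
      utils::write.table(row, path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    } else {
      jsonlite::write_json(as.list(row), path, auto_unbox = TRUE, digits = NA)
    }
  } else if (inherits(result, "cv_curve")) {
    tab <- data.frame(lambda = result$grid$values, value = result$values,
                      valid = is.finite(result$values))
    if (format == "tsv") {
      utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    } else {
      jsonlite::write_json(list(method = result$method,
                                lambda_hat = result$lambda_hat,
                                curve = tab, version = ver),
                           path, auto_unbox = TRUE, digits = NA)
    }
  } else {
    stop("unsupported result class: ", paste(class(result), collapse = "/"))
  }
  invisible(path)
}
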