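# Readers, writers and run provenance.  All matrices are sample-major
# (rows = individuals); delimited text with a header row, first column
# optionally sample identifiers.  Missing values are an input error: the
# model assumes complete data.

#' Read a response or predictor matrix from delimited text
#'
#' Accepts comma- or tab-separated files with a header row of variable names
#' and an optional leading column of sample identifiers (detected when the
#' first column is non-numeric).  Dosage matrices may be 0/1/2 integers.
#'
#' @param path File path.
#' @param role `"response"` or `"predictor"` (used in error messages).
#' @param inverse_rank_normal Apply the inverse rank-normal transformation
#'   to every column (responses only).
#' @return Numeric matrix with column names (and row names when sample
#'   identifiers are present).
#' @export
read_matrix <- function(path, role = c("response", "predictor"),
                        inverse_rank_normal = FALSE) {
  role <- match.arg(role)
  if (!file.exists(path)) stop(role, " file not found: ", path, call. = FALSE)
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, data.table = FALSE),
    error = function(e) stop("cannot parse ", role, " file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!nrow(dt) || !ncol(dt)) stop(role, " file ", path, " is empty", call. = FALSE)
  ids <- NULL
  if (!is.numeric(dt[[1L]])) {
    ids <- as.character(dt[[1L]])
    if (anyDuplicated(ids))
      stop("duplicated sample identifiers in ", role, " file (e.g. row ",
           anyDuplicated(ids), ")", call. = FALSE)
    dt <- dt[, -1L, drop = FALSE]
  }
  if (anyDuplicated(names(dt)))
    stop("duplicated ", role, " labels: ",
         names(dt)[anyDuplicated(names(dt))], call. = FALSE)
  for (j in seq_along(dt)) {
    if (!is.numeric(dt[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(dt[[j]]))) &
                     !is.na(dt[[j]]))[1L]
      stop(sprintf("non-numeric cell in %s file, column '%s'%s",
                   role, names(dt)[j],
                   if (!is.na(bad)) sprintf(", row %d", bad) else ""),
           call. = FALSE)
    }
  }
  m <- as.matrix(dt)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value in %s file at row %d, column '%s'",
                 role, idx[1L], colnames(m)[idx[2L]]), call. = FALSE)
  }
  if (inverse_rank_normal) m <- apply(m, 2L, inverse_rank_normal)
  rownames(m) <- ids
  m
}

#' Inverse rank-normal transformation
#'
#' Maps a numeric vector to exact normal quantiles of its (average, for
#' ties) ranks using the Blom offset: `qnorm((rank - 3/8) / (n + 1/4))`.
#'
#' @param x Numeric vector.
#' @param offset Rank offset constant (default 3/8).
#' @export
inverse_rank_normal <- function(x, offset = 3 / 8) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - offset) / (length(x) + 1 - 2 * offset))
}

#' Write the posterior summary file set
#'
#' Writes `mpip.csv`, `mepip.csv`, `associations.tsv`, `edges.tsv`,
#' `hotspots.tsv` and a JSON run manifest into `out_dir`.  Refuses to write
#' into a non-empty directory unless `force = TRUE`.
#'
#' @param fit A `sur_fit` object.
#' @param out_dir Output directory (created if absent).
#' @param t_edge,t_assoc Thresholds for the exported edge / association lists.
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(fit, out_dir, t_edge = 0.5, t_assoc = 0.5,
                          force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory ", out_dir, " is not empty (use force = TRUE)",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rn <- fit$labels$response
  pn <- fit$labels$predictor
  if (is.null(rn)) rn <- as.character(seq_len(nrow(fit$mpip)))
  if (is.null(pn)) pn <- as.character(seq_len(ncol(fit$mpip)))
  mpip <- fit$mpip; dimnames(mpip) <- list(rn, pn)
  mepip <- fit$mepip; dimnames(mepip) <- list(rn, rn)
  paths <- c(
    mpip = file.path(out_dir, "mpip.csv"),
    mepip = file.path(out_dir, "mepip.csv"),
    associations = file.path(out_dir, "associations.tsv"),
    edges = file.path(out_dir, "edges.tsv"),
    hotspots = file.path(out_dir, "hotspots.tsv"),
    manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(format(mpip, digits = 17, trim = TRUE), paths["mpip"])
  utils::write.csv(format(mepip, digits = 17, trim = TRUE), paths["mepip"])
  net <- threshold_network(fit, t_edge = t_edge, t_assoc = t_assoc)
  utils::write.table(net$associations, paths["associations"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(net$edges, paths["edges"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  hot <- data.frame(predictor = pn, E_pi = fit$pi_mean)
  utils::write.table(hot, paths["hotspots"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("qtlsur")),
    seed = fit$config$seed,
    n_iter = fit$config$n_iter, burnin = fit$config$burnin,
    covariance = fit$config$covariance,
    gamma_prior = fit$config$gamma_prior,
    n_chains = fit$config$n_chains,
    accept = as.list(round(fit$accept, 4)),
    elapsed_seconds = round(fit$elapsed, 2),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
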