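# Matrix and fit input/output: dense TSV/CSV with an NA token, sparse
# MatrixMarket, fit artifacts (loadings/factors as TSV, priors and trace as a
# JSON sidecar), and simulation truth sidecars.

#' Read a data matrix
#'
#' Reads a dense TSV/CSV matrix (no header; `na_token` cells become
#' unobserved) or a sparse MatrixMarket coordinate file. For MatrixMarket
#' input, entries absent from the file are treated as missing when
#' `zeros_as_missing = TRUE` and as observed zeros otherwise.
#'
#' @param path file path.
#' @param format `"auto"` (from the extension), `"tsv"`, `"csv"` or `"mtx"`.
#' @param na_token string marking missing cells in dense files.
#' @param zeros_as_missing for MatrixMarket input, whether unlisted cells are
#'   missing rather than zero.
#' @return An [observed_matrix].
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        na_token = "NA", zeros_as_missing = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", "tsv")
  }
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    dense <- as.matrix(m)
    if (zeros_as_missing) {
      mt <- methods::as(m, "TsparseMatrix")
      mask <- matrix(FALSE, nrow(dense), ncol(dense))
      mask[cbind(mt@i + 1L, mt@j + 1L)] <- TRUE
      return(observed_matrix(dense, mask))
    }
    return(observed_matrix(dense))
  }
  sep <- if (format == "csv") "," else "\t"
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty matrix file: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop("ragged input: row ", bad, " has ", widths[bad],
         " fields, expected ", widths[1])
  }
  vals <- matrix(NA_real_, length(fields), widths[1])
  for (i in seq_along(fields)) {
    row <- trimws(fields[[i]])
    isna <- row == na_token | row == ""
    num <- suppressWarnings(as.numeric(row))
    bad <- which(is.na(num) & !isna)
    if (length(bad) > 0) {
      stop("non-numeric cell at row ", i, ", column ", bad[1],
           ": \"", row[bad[1]], "\"")
    }
    num[isna] <- NA_real_
    vals[i, ] <- num
  }
  observed_matrix(vals)
}

#' Write a data matrix
#'
#' Writes the observed cells of a matrix to dense TSV/CSV (missing cells as
#' `na_token`) or to a MatrixMarket coordinate file (observed cells only, so
#' reading it back with `zeros_as_missing = TRUE` recovers the mask;
#' observed cells whose value is exactly zero are not representable in this
#' format).
#'
#' @param Y an [observed_matrix] (or plain matrix with `NA`s).
#' @param path output file path.
#' @inheritParams read_matrix
#' @return `path`, invisibly.
#' @export
write_matrix <- function(Y, path, format = c("auto", "tsv", "csv", "mtx"),
                         na_token = "NA") {
  format <- match.arg(format)
  Y <- as_observed(Y)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", "tsv")
  }
  if (format == "mtx") {
    idx <- which(Y$mask, arr.ind = TRUE)
    sm <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2],
                               x = Y$values[idx], dims = dim(Y$values))
    Matrix::writeMM(sm, path)
    return(invisible(path))
  }
  v <- Y$values
  v[!Y$mask] <- NA
  utils::write.table(v, path, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, col.names = FALSE, na = na_token)
  invisible(path)
}

serialize_prior <- function(g) {
  out <- unclass(g)
  out[!vapply(out, is.null, logical(1))]
}

deserialize_prior <- function(x) {
  switch(x$family,
    point_mass_zero  = prior_point_mass(),
    normal           = prior_normal(x$a),
    point_normal     = prior_point_normal(x$pi0, x$a),
    scale_mix_normal = prior_scale_mix_normal(unlist(x$grid),
                                              unlist(x$weights) /
                                                sum(unlist(x$weights)))
  )
}

#' Write fit artifacts
#'
#' Writes `loadings.tsv` and `factors.tsv` (one row per component: component
#' index, its pve, then the per-row values) and `fit.json` (dimensions,
#' priors, objective trace, precision structure).
#'
#' @param fit an `"ebmf_fit"` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  K <- ncol(fit$L)
  pve <- if (is.null(fit$pve)) compute_pve(fit) else fit$pve

  write_side <- function(mat, file, prefix) {
    df <- data.frame(factor = seq_len(K), pve = pve)
    if (K == 0) df <- df[0, , drop = FALSE]
    vals <- t(mat)
    colnames(vals) <- paste0(prefix, seq_len(nrow(mat)))
    df <- cbind(df, as.data.frame(vals))
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  write_side(fit$L, "loadings.tsv", "l")
  write_side(fit$FF, "factors.tsv", "f")

  meta <- list(
    n = nrow(fit$Y$values), p = ncol(fit$Y$values), K = K,
    tau_structure = fit$tau$structure,
    objective_trace = fit$objective_trace,
    pve = pve,
    priors_l = lapply(fit$priors_l, serialize_prior),
    priors_f = lapply(fit$priors_f, serialize_prior)
  )
  jsonlite::write_json(meta, file.path(dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read fit artifacts back
#'
#' Reads the artifacts written by [write_fit]. Only the point estimates are
#' stored, so the result supports reconstruction/evaluation but not further
#' fitting.
#'
#' @param dir directory holding `loadings.tsv`, `factors.tsv`, `fit.json`.
#' @return list with `L` (n x K), `FF` (p x K), `pve`, `objective_trace`,
#'   `priors_l`, `priors_f`, `K`.
#' @export
read_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "fit.json"), simplifyVector = TRUE)
  read_side <- function(file, len) {
    df <- utils::read.table(file.path(dir, file), header = TRUE, sep = "\t")
    if (nrow(df) == 0) return(matrix(0, len, 0))
    t(as.matrix(df[, -(1:2), drop = FALSE]))
  }
  pl <- meta$priors_l
  pf <- meta$priors_f
  if (is.data.frame(pl)) pl <- split(pl, seq_len(nrow(pl)))
  if (is.data.frame(pf)) pf <- split(pf, seq_len(nrow(pf)))
  list(L = read_side("loadings.tsv", meta$n),
       FF = read_side("factors.tsv", meta$p),
       pve = meta$pve,
       objective_trace = meta$objective_trace,
       priors_l = pl, priors_f = pf,
       K = meta$K)
}

#' Write a simulation with its truth sidecar
#'
#' Writes the simulated matrix (TSV or MatrixMarket) plus `truth.json` with
#' the true loadings, factors, noise precision and seed.
#'
#' @param sim a `"sim_truth"` object.
#' @param dir output directory.
#' @param format `"tsv"` or `"mtx"` for the data matrix.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(sim$Y, file.path(dir, paste0("y.", format)), format)
  jsonlite::write_json(
    list(design = sim$design, seed = sim$seed, tau = sim$tau_true,
         L_true = sim$L_true, F_true = sim$F_true),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' Read a simulation truth sidecar
#'
#' @param path path to a `truth.json` written by [write_sim].
#' @return list with `L_true`, `F_true`, `tau`, `seed`, `design`.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$L_true <- as.matrix(tr$L_true)
  tr$F_true <- as.matrix(tr$F_true)
  tr
}
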