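#' Construct a signed metagene signature
#'
#' A signature is an ordered gene list with coefficients of +1 (high
#' expression adverse) or -1 (low expression adverse) and, once
#' trained, a score cutoff separating High from Low risk.
#'
#' @param genes Character vector of gene ids.
#' @param coefficients Integer vector of +1/-1, one per gene.
#' @param cutoff Score cutoff (NA until trained).
#' @param provenance Optional list of thresholds/seeds recorded with
#'   the model.
#' @return A `signature_model`.
#' @export
signature_model <- function(genes, coefficients, cutoff = NA_real_,
                            provenance = list()) {
  assert_that_(length(genes) >= 1, "a signature needs at least one gene")
  assert_that_(length(coefficients) == length(genes),
               "one coefficient per gene required")
  assert_that_(all(coefficients %in% c(-1, 1)),
               "coefficients must be +1 or -1")
  assert_that_(!anyDuplicated(genes), "duplicate genes in signature")
  structure(
    list(genes = as.character(genes),
         coefficients = as.integer(coefficients),
         cutoff = cutoff, provenance = provenance),
    class = "signature_model"
  )
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d genes (%d up-risk, %d down-risk); cutoff %s\n",
              length(x$genes), sum(x$coefficients == 1),
              sum(x$coefficients == -1),
              ifelse(is.na(x$cutoff), "untrained", format(x$cutoff))))
  invisible(x)
}

#' Serialize / deserialize a signature model
#'
#' JSON round-trip of genes, coefficients, cutoff and provenance.
#'
#' @param model A [signature_model()].
#' @param path File path.
#' @return `write_signature()` returns `path` invisibly;
#'   `read_signature()` the model.
#' @export
write_signature <- function(model, path) {
  jsonlite::write_json(
    list(genes = model$genes, coefficients = model$coefficients,
         cutoff = model$cutoff, provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  signature_model(x$genes, x$coefficients,
                  cutoff = x$cutoff %||% NA_real_,
                  provenance = as.list(x$provenance))
}

#' Rescale each sample's signature-gene expression to 0-100
#'
#' Per sample (column): `(A - min(A)) / (max(A) - min(A)) * 100`, so
#' the minimum maps to 0 and the maximum to 100.
#'
#' @param expr Genes x samples numeric matrix (already subset to the
#'   signature genes).
#' @return Matrix of the same shape on the 0-100 scale.
#' @export
#' @examples
#' rescale_0_100(cbind(s1 = c(2, 4, 6)))
rescale_0_100 <- function(expr) {
  rng <- apply(expr, 2, range)
  flat <- which(rng[2, ] - rng[1, ] == 0)
  if (length(flat) > 0) {
    abort(paste0("constant expression within sample(s): ",
                 paste(colnames(expr)[flat], collapse = ", ")))
  }
  sweep(sweep(expr, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], "/") * 100
}

#' Score samples with a signed metagene
#'
#' The per-sample score is the mean expression of the +1 genes times
#' their signature fraction minus the mean expression of the -1 genes
#' times theirs: `(sum pos)/N - (sum neg)/N` with `N = Np + Nn`. By
#' default the signature-gene submatrix is first rescaled per sample to
#' 0-100 to widen the score's dynamic range.
#'
#' If more than 10% of the signature genes are missing from the matrix
#' the call errors; otherwise the missing genes are dropped and N, Np,
#' Nn renormalized (with a warning).
#'
#' @param expr Probes (or genes) x samples expression matrix.
#' @param model A [signature_model()].
#' @param probe_map Optional `probe`/`gene` map.
#' @param rescale Rescale the submatrix per sample first (default TRUE).
#' @return Tibble: `sample`, `score`.
#' @export
compute_score <- function(expr, model, probe_map = NULL, rescale = TRUE) {
  gexpr <- if (is.null(probe_map)) expr else collapse_probes(expr, probe_map)
  present <- model$genes %in% rownames(gexpr)
  if (mean(present) < 0.9) {
    abort(sprintf("%d of %d signature genes missing from expression (> 10%%)",
                  sum(!present), length(model$genes)))
  }
  if (any(!present)) {
    warn(sprintf("%d signature gene(s) missing; renormalizing to %d genes",
                 sum(!present), sum(present)))
  }
  genes <- model$genes[present]
  coefs <- model$coefficients[present]
  sub <- gexpr[genes, , drop = FALSE]
  if (rescale) sub <- rescale_0_100(sub)
  n_total <- length(genes)
  score <- as.numeric(crossprod(sub, coefs)) / n_total
  tibble(sample = colnames(sub), score = score)
}
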