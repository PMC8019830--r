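## Variance components and model specification constructors, plus the
## YAML config reader.

.chkSPD <- function(M, what) {
  if (max(abs(M - t(M))) > 1e-8) stop(what, " must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop(what, " must be positive definite")
  invisible(TRUE)
}

#' Variance components
#'
#' Only the components a family uses need to be supplied; validity of
#' the combination is checked when the equations are assembled.  The
#' direct/maternal covariance matrix and the ratio coefficients
#' (lambda, alpha, sigmaE2 * G^-1) are derived on demand.
#'
#' @param sigmaU2,sigmaE2,sigmaP2,sigmaM2,sigmaUM,sigmaMPE2 scalar
#'   components (see [VarianceComponents-class]).
#' @param G0,R0 trait covariance matrices for multiple-trait models.
#' @return a [VarianceComponents-class].
#' @examples
#' varComp(sigmaU2 = 0.3, sigmaE2 = 0.7)
#' @export
varComp <- function(sigmaU2 = numeric(0), sigmaE2 = numeric(0),
                    sigmaP2 = numeric(0), sigmaM2 = numeric(0),
                    sigmaUM = numeric(0), sigmaMPE2 = numeric(0),
                    G0 = NULL, R0 = NULL) {
  num <- function(x) as.numeric(x)
  for (v in list(sigmaU2, sigmaP2, sigmaM2, sigmaMPE2))
    if (length(v) && v <= 0) stop("variance components must be positive")
  if (length(sigmaE2) && sigmaE2 < 0)
    stop("residual variance must be non-negative")
  if (!is.null(G0)) .chkSPD(G0 <- as.matrix(G0), "G0") else G0 <- matrix(numeric(0), 0, 0)
  if (!is.null(R0)) .chkSPD(R0 <- as.matrix(R0), "R0") else R0 <- matrix(numeric(0), 0, 0)
  new("VarianceComponents", sigmaU2 = num(sigmaU2), sigmaE2 = num(sigmaE2),
      sigmaP2 = num(sigmaP2), sigmaM2 = num(sigmaM2), sigmaUM = num(sigmaUM),
      sigmaMPE2 = num(sigmaMPE2), G0 = G0, R0 = R0)
}

## Direct/maternal 2x2 genetic covariance, checked positive definite.
.maternalG2 <- function(vc, correlated) {
  um <- if (correlated && length(vc@sigmaUM)) vc@sigmaUM else 0
  G2 <- matrix(c(vc@sigmaU2, um, um, vc@sigmaM2), 2, 2)
  .chkSPD(G2, "the direct/maternal covariance matrix")
  G2
}

#' Model specification
#'
#' @param family model family, one of `"basic"`, `"multitrait"`,
#'   `"repeatability"`, `"maternal_uncorrelated"`,
#'   `"maternal_correlated"`, `"groups"`, `"gblup"`, `"ssgblup"`.
#' @param fixedFactors names of fixed factor/covariate columns in the
#'   phenotype table (character columns become factors, numeric ones
#'   covariates); empty means a single overall mean.
#' @param traits trait column names.
#' @param includeMPE add a maternal permanent-environment effect
#'   (maternal families).
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(family, fixedFactors = character(0), traits = "y",
                      includeMPE = family %in% c("maternal_uncorrelated",
                                                 "maternal_correlated")) {
  kin <- switch(family, gblup = "genomic", ssgblup = "hybrid", "pedigree")
  new("ModelSpec", family = family,
      fixedFactors = as.character(fixedFactors),
      traits = as.character(traits), includeMPE = isTRUE(includeMPE),
      kinshipSource = kin)
}

#' Default variance components per model family
#'
#' The package's reference conditions: heritability 0.3 for
#' single-trait families, a moderate permanent-environment share for
#' repeatability, a negative direct-maternal covariance typical of
#' growth traits, and two genetically correlated traits for the
#' multiple-trait family.
#'
#' @param family model family name.
#' @return a [VarianceComponents-class].
#' @export
defaultVarComp <- function(family) {
  switch(family,
    basic = , groups = , gblup = , ssgblup =
      varComp(sigmaU2 = 0.3, sigmaE2 = 0.7),
    repeatability =
      varComp(sigmaU2 = 0.3, sigmaP2 = 0.2, sigmaE2 = 0.5),
    maternal_uncorrelated =
      varComp(sigmaU2 = 0.3, sigmaM2 = 0.12, sigmaMPE2 = 0.1,
              sigmaE2 = 0.48),
    maternal_correlated =
      varComp(sigmaU2 = 0.3, sigmaM2 = 0.12, sigmaUM = -0.06,
              sigmaMPE2 = 0.1, sigmaE2 = 0.48),
    multitrait =
      varComp(G0 = matrix(c(2, 0.5, 0.5, 1), 2, 2),
              R0 = matrix(c(4, 1, 1, 3), 2, 2)),
    stop("unknown family: ", family))
}

#' Read variance components from a YAML/JSON config
#'
#' Recognized keys mirror the [VarianceComponents-class] slots:
#' `sigma_u2`, `sigma_e2`, `sigma_p2`, `sigma_m2`, `sigma_um`,
#' `sigma_mpe2`, and `G0` / `R0` as lists of rows.
#'
#' @param path config file path.
#' @return a [VarianceComponents-class].
#' @export
readVarianceComponents <- function(path) {
  cfg <- yaml::read_yaml(path)
  asMat <- function(x) if (is.null(x)) NULL else do.call(rbind, lapply(x, as.numeric))
  varComp(sigmaU2 = as.numeric(cfg$sigma_u2 %||% numeric(0)),
          sigmaE2 = as.numeric(cfg$sigma_e2 %||% numeric(0)),
          sigmaP2 = as.numeric(cfg$sigma_p2 %||% numeric(0)),
          sigmaM2 = as.numeric(cfg$sigma_m2 %||% numeric(0)),
          sigmaUM = as.numeric(cfg$sigma_um %||% numeric(0)),
          sigmaMPE2 = as.numeric(cfg$sigma_mpe2 %||% numeric(0)),
          G0 = asMat(cfg$G0), R0 = asMat(cfg$R0))
}

#' Write variance components to a YAML config
#'
#' @param vc a [VarianceComponents-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeVarianceComponents <- function(vc, path) {
  out <- list()
  put <- function(key, val) if (length(val)) out[[key]] <<- as.numeric(val)
  put("sigma_u2", vc@sigmaU2); put("sigma_e2", vc@sigmaE2)
  put("sigma_p2", vc@sigmaP2); put("sigma_m2", vc@sigmaM2)
  put("sigma_um", vc@sigmaUM); put("sigma_mpe2", vc@sigmaMPE2)
  if (length(vc@G0)) out$G0 <- lapply(seq_len(nrow(vc@G0)), function(i) as.numeric(vc@G0[i, ]))
  if (length(vc@R0)) out$R0 <- lapply(seq_len(nrow(vc@R0)), function(i) as.numeric(vc@R0[i, ]))
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
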