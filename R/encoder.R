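#' Shared covariate encoder
#'
#' Every model in the package (Cox, trees, forests, neural networks, the
#' propensity and recommendation-behavior logistic regressions) consumes the
#' same numeric design matrix, produced by a single encoder fitted once on a
#' covariate table. Continuous covariates are standardized to mean 0 / sd 1
#' (using the statistics of the data the encoder was built on); categorical
#' covariates are one-hot encoded with the first level as reference.
#'
#' @param covariates data.frame of covariates; character columns are treated
#'   as categorical (converted to factors with levels in first-appearance
#'   order unless already factors), numeric columns as continuous.
#' @return an object of class `svt_encoder`.
#' @export
build_encoder <- function(covariates) {
  stopifnot(is.data.frame(covariates), nrow(covariates) > 0L)
  cols <- names(covariates)
  spec <- lapply(cols, function(cn) {
    x <- covariates[[cn]]
    if (is.numeric(x)) {
      s <- stats::sd(x)
      list(kind = "continuous", center = mean(x), scale = if (s > 0) s else 1)
    } else {
      f <- if (is.factor(x)) x else factor(x, levels = unique(as.character(x)))
      list(kind = "categorical", levels = levels(f))
    }
  })
  names(spec) <- cols
  colnames_out <- unlist(lapply(cols, function(cn) {
    sp <- spec[[cn]]
    if (sp$kind == "continuous") cn else {
      lv <- sp$levels
      if (length(lv) > 1L) paste(cn, lv[-1L], sep = ".") else character(0)
    }
  }))
  structure(list(columns = cols, spec = spec, encoded_names = colnames_out),
            class = "svt_encoder")
}

#' Encode a covariate table with a fitted encoder
#'
#' @param encoder a `svt_encoder` from [build_encoder()].
#' @param covariates data.frame with the same columns the encoder was built on.
#' @return numeric matrix with one row per input row.
#' @export
encode_covariates <- function(encoder, covariates) {
  stopifnot(inherits(encoder, "svt_encoder"))
  missing_cols <- setdiff(encoder$columns, names(covariates))
  if (length(missing_cols) > 0L) {
    stop("covariate table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(covariates)
  blocks <- lapply(encoder$columns, function(cn) {
    sp <- encoder$spec[[cn]]
    x <- covariates[[cn]]
    if (sp$kind == "continuous") {
      if (!is.numeric(x)) stop("column '", cn, "' must be numeric")
      m <- matrix((x - sp$center) / sp$scale, ncol = 1)
      colnames(m) <- cn
      m
    } else {
      xs <- as.character(x)
      bad <- setdiff(unique(xs), sp$levels)
      if (length(bad) > 0L) {
        stop("column '", cn, "' has levels outside the training schema: ",
             paste(bad, collapse = ", "))
      }
      lv <- sp$levels
      if (length(lv) == 1L) return(matrix(numeric(0), nrow = n, ncol = 0))
      m <- vapply(lv[-1L], function(l) as.numeric(xs == l), numeric(n))
      m <- matrix(m, nrow = n)
      colnames(m) <- paste(cn, lv[-1L], sep = ".")
      m
    }
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- NULL
  out
}

# Map each encoded column back to its source covariate (used when Shapley
# attributions of one-hot columns are pooled per variable).
encoder_groups <- function(encoder) {
  grp <- unlist(lapply(encoder$columns, function(cn) {
    sp <- encoder$spec[[cn]]
    k <- if (sp$kind == "continuous") 1L else max(length(sp$levels) - 1L, 0L)
    rep(cn, k)
  }))
  stats::setNames(grp, encoder$encoded_names)
}
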