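## Path-dependent TreeSHAP for xgboost tree ensembles, computed in double
## precision from the dumped trees so that the additive decomposition
## (base value + per-feature contributions = prediction) holds to numerical
## tolerance far tighter than the float32 arithmetic of the native
## predcontrib path.

## xgboost stores features and thresholds as float32 and compares in
## float32; round-trip through 4-byte floats so double arithmetic agrees
## with the library's traversal bit-for-bit.
.asFloat32 <- function(x) {
    out <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
                   what = "numeric", size = 4L, n = length(x))
    out[is.nan(out)] <- NA_real_
    out
}

.parseTrees <- function(model, featureNames) {
    dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
    base <- as.numeric(
        xgboost::xgb.config(model)$learner$learner_model_param$base_score)
    trees <- lapply(split(dt, dt$Tree), function(td) {
        td <- td[order(td$Node), ]
        idx <- function(ids) match(ids, td$ID)
        leaf <- td$Feature == "Leaf"
        list(featIdx = ifelse(leaf, NA_integer_,
                              match(td$Feature, featureNames)),
             split = .asFloat32(td$Split),
             yes = idx(td$Yes), no = idx(td$No), missing = idx(td$Missing),
             value = ifelse(leaf, td$Gain, NA_real_),
             cover = td$Cover)
    })
    list(trees = trees, base = base, featureNames = featureNames)
}

## cover-weighted expected value of one tree (the bias contribution)
.treeExpected <- function(tr, j = 1L) {
    if (is.na(tr$featIdx[j]) ) return(tr$value[j])
    (tr$cover[tr$yes[j]] * .treeExpected(tr, tr$yes[j]) +
     tr$cover[tr$no[j]] * .treeExpected(tr, tr$no[j])) / tr$cover[j]
}

.treePredict <- function(tr, x) {
    j <- 1L
    repeat {
        f <- tr$featIdx[j]
        if (is.na(f)) return(tr$value[j])
        xv <- x[f]
        j <- if (is.na(xv)) tr$missing[j]
             else if (xv < tr$split[j]) tr$yes[j] else tr$no[j]
    }
}

## Lundberg's path-dependent algorithm, written recursively with copied
## paths (trees here are tiny: <= 5 leaves, so path copies are cheap).
## Path state: parallel vectors d (feature index; the root element carries a
## dummy 0), z (zero fraction), o (one fraction), w (permutation weights).
.shapRecurse <- function(tr, x, j, d, z, o, w, pd, pz, po, phi) {
    ## EXTEND
    l <- length(w)
    d <- c(d, pd); z <- c(z, pz); o <- c(o, po)
    w <- c(w, if (l == 0) 1 else 0)
    if (l > 0) for (i in l:1) {
        w[i + 1] <- w[i + 1] + po * w[i] * i / (l + 1)
        w[i] <- pz * w[i] * (l + 1 - i) / (l + 1)
    }
    f <- tr$featIdx[j]
    if (is.na(f)) {
        ## leaf: attribute to every feature on the path
        l <- length(w)
        if (l >= 2) for (i in 2:l) {
            ## sum of weights after unwinding element i
            n <- w[l]; total <- 0
            if (o[i] != 0) {
                for (jj in (l - 1):1) {
                    tmp <- n * l / (jj * o[i])
                    total <- total + tmp
                    n <- w[jj] - tmp * z[i] * (l - jj) / l
                }
            } else {
                for (jj in (l - 1):1)
                    total <- total + w[jj] * l / (z[i] * (l - jj))
            }
            phi[d[i]] <- phi[d[i]] + total * (o[i] - z[i]) * tr$value[j]
        }
        return(phi)
    }
    xv <- x[f]
    hot <- if (is.na(xv)) tr$missing[j]
           else if (xv < tr$split[j]) tr$yes[j] else tr$no[j]
    cold <- if (hot == tr$yes[j]) tr$no[j] else tr$yes[j]
    iz <- 1; io <- 1
    k <- which(d == f)
    k <- k[k > 1]
    if (length(k)) {
        k <- k[1]
        iz <- z[k]; io <- o[k]
        ## UNWIND element k
        l <- length(w)
        n <- w[l]
        if (io != 0) {
            for (jj in (l - 1):1) {
                t <- w[jj]
                w[jj] <- n * l / (jj * io)
                n <- t - w[jj] * iz * (l - jj) / l
            }
        } else {
            for (jj in (l - 1):1)
                w[jj] <- w[jj] * l / (iz * (l - jj))
        }
        d <- d[-k]; z <- z[-k]; o <- o[-k]; w <- w[-l]
    }
    phi <- .shapRecurse(tr, x, hot, d, z, o, w, f,
                        iz * tr$cover[hot] / tr$cover[j], io, phi)
    phi <- .shapRecurse(tr, x, cold, d, z, o, w, f,
                        iz * tr$cover[cold] / tr$cover[j], 0, phi)
    phi
}

#' Shapley-value contributions for a tree ensemble
#'
#' Computes exact path-dependent TreeSHAP contributions for every row of a
#' feature matrix, in double precision, directly from the dumped trees of an
#' xgboost model. The last column (\code{BIAS}) is the base value: the
#' model's intercept plus the cover-weighted expected value of every tree.
#' For each row, base value + contributions reproduces the (double
#' precision) model prediction.
#'
#' @param model an \code{xgb.Booster} (e.g. the refit model from
#'   [trainGbmCv()]).
#' @param X numeric matrix with the model's feature columns (NA allowed).
#' @return matrix with one column per feature plus \code{BIAS}.
#' @export
treeShap <- function(model, X) {
    X <- as.matrix(X)
    cn <- colnames(X); rn <- rownames(X)
    X <- matrix(.asFloat32(X), nrow(X), ncol(X), dimnames = list(rn, cn))
    pt <- .parseTrees(model, colnames(X))
    p <- ncol(X)
    phi <- matrix(0, nrow(X), p + 1,
                  dimnames = list(rownames(X), c(colnames(X), "BIAS")))
    expected <- vapply(pt$trees, .treeExpected, numeric(1))
    phi[, p + 1] <- pt$base + sum(expected)
    for (i in seq_len(nrow(X))) {
        x <- X[i, ]
        contrib <- numeric(p)
        for (ti in seq_along(pt$trees))
            contrib <- .shapRecurse(pt$trees[[ti]], x, 1L, integer(0),
                                    numeric(0), numeric(0), numeric(0),
                                    0L, 1, 1, contrib)
        phi[i, seq_len(p)] <- contrib
    }
    phi
}

#' Double-precision prediction from the dumped trees
#'
#' Traverses the dumped trees in double precision; used to verify SHAP
#' additivity independently of xgboost's float32 prediction path.
#'
#' @inheritParams treeShap
#' @return numeric vector of predictions.
#' @export
predictFromTrees <- function(model, X) {
    X <- as.matrix(X)
    cn <- colnames(X); rn <- rownames(X)
    X <- matrix(.asFloat32(X), nrow(X), ncol(X), dimnames = list(rn, cn))
    pt <- .parseTrees(model, colnames(X))
    vapply(seq_len(nrow(X)), function(i) {
        pt$base + sum(vapply(pt$trees, .treePredict, numeric(1), X[i, ]))
    }, numeric(1))
}
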