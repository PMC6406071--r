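#' Parametric stability-scoring component
#'
#' The single scoring curve used by every component of the reference-gene
#' suitability system. For a scored variable `x` the component value is
#'
#' \deqn{S = \frac{100}{1 + Sq \cdot \left(\frac{\max(x - IV, 0)}{IP - IV}\right)^{CS}}}
#'
#' a reversed sigmoid on the 0-100 scale. `x <= IV` (the "ideal value")
#' saturates at 100; at `x = IP` (the "inflection point") with `sq = 1` the
#' score is exactly 50; larger `cs` ("curve slope") makes the drop past the
#' ideal region steeper; `sq` ("squeeze") rescales the penalised region
#' without moving the saturation boundary.
#'
#' @param x Numeric vector of scored variable values. Must be finite; a
#'   non-finite value indicates an upstream feature-extraction fault and is
#'   an error rather than silently propagated.
#' @param iv Ideal value: scores saturate at 100 for `x <= iv`.
#' @param ip Inflection point; must exceed `iv`.
#' @param cs Curve slope exponent, positive.
#' @param sq Squeeze factor, positive. Defaults to 1.
#' @return Numeric vector of scores in `[0, 100]`.
#' @examples
#' componentScore(0.3, iv = 0.1, ip = 0.3, cs = 2)      # 50 at the inflection
#' componentScore(0.05, iv = 0.1, ip = 0.3, cs = 2)     # 100 in the ideal region
#' componentScore(3, iv = 1, ip = 3, cs = 2, sq = 0.4)  # 100/1.4
#' @export
componentScore <- function(x, iv, ip, cs, sq = 1) {
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (anyNA(x) || any(!is.finite(x)))
    stop("non-finite scored variable 'x': upstream feature extraction ",
         "produced an invalid value")
  checkScoringParams(iv, ip, cs, sq)
  100 / (1 + sq * (pmax(x - iv, 0) / (ip - iv))^cs)
}

checkScoringParams <- function(iv, ip, cs, sq, ca = 0, w = 1) {
  if (!(is.numeric(iv) && is.numeric(ip) && ip > iv))
    stop("inflection point 'ip' must exceed ideal value 'iv'")
  if (!(cs > 0)) stop("curve slope 'cs' must be positive")
  if (!(sq > 0)) stop("squeeze 'sq' must be positive")
  if (!(ca >= 0)) stop("constant add 'ca' must be non-negative")
  if (!(w > 0)) stop("weight 'w' must be positive")
  invisible(TRUE)
}

#' Aggregate component scores into the expression score
#'
#' Combines one score per registry instance into the overall expression
#' score: a weighted geometric mean of `min(S_i + CA_i, 100)` with weight
#' exponents `W_i`, normalised by the total weight. `CA_i` is a constant
#' summand that softens the impact of a single zero component; components
#' with `CA = 0` retain veto power (a zero score zeroes the aggregate).
#' The clamp at 100 preserves the 0-100 scale of the aggregate.
#'
#' @param scores Named numeric vector of component scores in `[0, 100]`,
#'   names matching `instances$instance`.
#' @param instances Instance table from [expandRegistry()]: a data.frame
#'   with at least columns `instance`, `ca`, `w`.
#' @return The aggregate expression score in `[0, 100]`.
#' @examples
#' inst <- data.frame(instance = c("a", "b"), ca = 0, w = 1)
#' aggregateExpressionScore(c(a = 50, b = 100), inst)  # sqrt(50 * 100)
#' @export
aggregateExpressionScore <- function(scores, instances) {
  stopifnot(is.data.frame(instances),
            all(c("instance", "ca", "w") %in% names(instances)))
  missing <- setdiff(instances$instance, names(scores))
  if (length(missing))
    stop("missing component instance(s): ", paste(missing, collapse = ", "))
  s <- as.numeric(scores[instances$instance])
  if (anyNA(s)) stop("NA component score for instance(s): ",
                     paste(instances$instance[is.na(s)], collapse = ", "))
  term <- pmin(s + instances$ca, 100)
  if (any(term < 0)) stop("component score below -CA encountered")
  if (any(term == 0)) return(0)
  exp(sum(instances$w * log(term)) / sum(instances$w))
}

#' Anti-scorings for mutation burden, isoforms and pseudogenes
#'
#' Applies the parametric scoring curve to the three gene-level
#' "anti-scoring" variables: the percentile of the gene's somatic-mutation
#' rate among all genes of the condition, the number of annotated
#' transcript isoforms, and the number of pseudogenes. Each anti-score is
#' on `[0, 100]` and later multiplies (scaled by 1/100) the expression
#' score into the final score.
#'
#' @param mutationPercentile Numeric vector in `[0, 100]`
#'   (see [mutationPercentile()]); `NA` allowed, handled per `naAction`.
#' @param nIsoforms,nPseudogenes Non-negative integer vectors; `NA`
#'   allowed, handled per `naAction`.
#' @param config Scoring configuration (see [defaultScoringConfig()]);
#'   supplies the anti-scoring curve parameters.
#' @param naAction `"neutral"` scores missing annotation as 100 with a
#'   warning; `"error"` fails.
#' @return A data.frame with columns `s_mut`, `s_isoforms`,
#'   `s_pseudogenes`.
#' @export
antiScores <- function(mutationPercentile, nIsoforms, nPseudogenes,
                       config = defaultScoringConfig(),
                       naAction = c("neutral", "error")) {
  naAction <- match.arg(naAction)
  fill <- function(x, what) {
    if (anyNA(x)) {
      if (naAction == "error") stop("missing ", what, " annotation")
      warning("missing ", what, " annotation for ", sum(is.na(x)),
              " gene(s); assigned neutral anti-score 100", call. = FALSE)
    }
    x
  }
  mp <- as.numeric(fill(mutationPercentile, "mutation"))
  ni <- as.numeric(fill(nIsoforms, "isoform-count"))
  np <- as.numeric(fill(nPseudogenes, "pseudogene-count"))
  if (any(mp < 0 | mp > 100, na.rm = TRUE))
    stop("'mutationPercentile' must lie in [0, 100]")
  if (any(ni < 0, na.rm = TRUE) || any(np < 0, na.rm = TRUE))
    stop("isoform/pseudogene counts must be non-negative")
  one <- function(x, p) {
    out <- rep(100, length(x))
    ok <- !is.na(x)
    out[ok] <- componentScore(x[ok], p$iv, p$ip, p$cs, p$sq)
    out
  }
  a <- config$anti
  data.frame(
    s_mut         = one(mp, a$S_Mut),
    s_isoforms    = one(ni, a$S_Isoforms),
    s_pseudogenes = one(np, a$S_Pseudogenes)
  )
}

#' Final combined suitability score
#'
#' Multiplies the expression score by the three anti-scorings. Each
#' anti-score is divided by 100 so the product stays on the 0-100 scale of
#' the expression score; rankings are unchanged by this normalisation.
#'
#' @param sExp,sMut,sIsoforms,sPseudogenes Numeric vectors in `[0, 100]`.
#' @return Numeric vector of final scores in `[0, 100]`.
#' @export
finalScore <- function(sExp, sMut, sIsoforms, sPseudogenes) {
  for (v in list(sExp, sMut, sIsoforms, sPseudogenes))
    if (any(v < 0 | v > 100, na.rm = TRUE))
      stop("all score inputs must lie in [0, 100]")
  sExp * (sMut / 100) * (sIsoforms / 100) * (sPseudogenes / 100)
}

#' Pan-cancer aggregation of per-condition scores
#'
#' Aggregates one gene's per-condition combined expression-and-mutation
#' values across conditions with a negative-exponent power mean:
#'
#' \deqn{S^{Exp\&Mut}_{Pan} = \left(\frac{1}{M}\sum_j (v_j + CA)^k\right)^{1/k}, \quad
#'       v_j = S^{Exp}_j \cdot S^{Mut}_j / 100}
#'
#' With `k = -0.4` the aggregate behaves like a harmonic-type mean: a
#' single weak condition drags the pan-cancer score down, rewarding genes
#' that are consistently stable. Note the formula carries the `+CA` offset
#' through: identical per-condition values `v` aggregate to `v + CA`.
#' The final pan-cancer score multiplies by the (1/100-scaled) isoform and
#' pseudogene anti-scores.
#'
#' @param sExp,sMut Numeric vectors, one entry per condition, in `[0, 100]`.
#' @param sIsoforms,sPseudogenes Scalar anti-scores in `[0, 100]`
#'   (condition-independent annotation).
#' @param k Power-mean exponent; default -0.4.
#' @param ca Constant add inside the power mean; default 12.
#' @return A list with `sExpMutPan`, `sFinalPan`, `m` (number of
#'   conditions), `k`, `ca`.
#' @examples
#' panCancerScore(rep(70, 12), rep(100, 12))$sExpMutPan  # 70 + 12
#' @export
panCancerScore <- function(sExp, sMut, sIsoforms = 100, sPseudogenes = 100,
                           k = -0.4, ca = 12) {
  if (length(sExp) == 0L) stop("no per-condition scores supplied")
  if (length(sExp) != length(sMut))
    stop("'sExp' and 'sMut' must have one entry per condition")
  if (k == 0) stop("power-mean exponent 'k' must be non-zero")
  v <- sExp * sMut / 100
  pan <- mean((v + ca)^k)^(1 / k)
  list(
    sExpMutPan = pan,
    sFinalPan  = pan * (sIsoforms / 100) * (sPseudogenes / 100),
    m = length(v), k = k, ca = ca
  )
}
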