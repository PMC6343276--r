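# Liu-type moment-matching approximation (noncentral chi-square matched
# on skewness/kurtosis) to the upper tail of sum_k lambda_k chi2_1.
.liuPvalue <- function(q, lambda) {
    c1 <- sum(lambda)
    c2 <- sum(lambda^2)
    c3 <- sum(lambda^3)
    c4 <- sum(lambda^4)
    s1 <- c3 / c2^1.5
    s2 <- c4 / c2^2
    if (s1^2 > s2) {
        a <- 1 / (s1 - sqrt(s1^2 - s2))
        delta <- s1 * a^3 - a^2
        l <- a^2 - 2 * delta
    } else {
        l <- 1 / s2
        delta <- 0
    }
    muQ <- c1
    sigmaQ <- sqrt(2 * c2)
    muX <- l + delta
    sigmaX <- sqrt(2 * (l + 2 * delta))
    x <- (q - muQ) / sigmaQ * sigmaX + muX
    pchisq(x, df = l, ncp = delta, lower.tail = FALSE)
}

# Imhof characteristic-function inversion for P(sum lambda_k chi2_1 >= q):
#   1/2 + (1/pi) * Int_0^Inf sin(theta(u)) / (u * rho(u)) du
# with theta(u) = (1/2) sum atan(lambda u) - q u / 2 and
# rho(u) = prod (1 + lambda^2 u^2)^(1/4).
.imhofPvalue <- function(q, lambda, absTol = 1e-9) {
    integrand <- function(u) {
        lu <- outer(lambda, u)
        theta <- 0.5 * colSums(atan(lu)) - 0.5 * q * u
        rho <- exp(0.25 * colSums(log1p(lu^2)))
        out <- sin(theta) / (u * rho)
        # continuous limit at u = 0
        out[u == 0] <- 0.5 * (sum(lambda) - q)
        out
    }
    val <- integrate(integrand, 0, Inf, subdivisions = 1000L,
                     rel.tol = 1e-10, abs.tol = absTol,
                     stop.on.error = TRUE)
    list(p = 0.5 + val$value / pi, error = val$abs.error / pi)
}

#' Tail probability of a weighted sum of chi-square(1) variables
#'
#' Computes `P(sum_k lambda_k chi2_1 >= q)`, the null tail probability of
#' the SKAT statistic, by numerical inversion of the characteristic
#' function (Imhof-type integral) with an accuracy target of 1e-6. When
#' the inversion fails or returns a value outside `[0, 1]` (which can
#' happen deep in the tail), a Liu-type moment-matching approximation is
#' used instead and flagged in the result.
#'
#' @param q observed statistic (scalar, >= 0).
#' @param lambda positive mixture weights (the kernel eigenvalues).
#' @param accuracy absolute accuracy target for the inversion
#'   (default 1e-6).
#' @return A list with elements `p` (the p-value, clamped to `[0, 1]`)
#'   and `method` (`"imhof"` or `"liu"`).
#' @examples
#' pMixtureChisq(3.84, 1)$p          # chi2_1 tail
#' pMixtureChisq(5, c(2, 1, 0.5))$p
#' @export
pMixtureChisq <- function(q, lambda, accuracy = 1e-6) {
    lambda <- lambda[lambda > 0]
    if (!length(lambda))
        stop("at least one positive mixture weight is required")
    if (q <= 0)
        return(list(p = 1, method = "exact"))
    res <- tryCatch(.imhofPvalue(q, lambda, absTol = accuracy / 10),
                    error = function(e) NULL)
    if (!is.null(res) && res$error <= accuracy &&
        res$p > accuracy && res$p < 1 + accuracy)
        return(list(p = min(max(res$p, 0), 1), method = "imhof"))
    list(p = .liuPvalue(q, lambda), method = "liu")
}
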