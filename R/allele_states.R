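# Allele-specific CNV/LOH inference from inherited heterozygous variants,
# and the ancestry partial order over allele states.

#' Expected allele fraction of an inherited het variant under a purity mixture
#'
#' For a germline heterozygous variant carried on `m` of `c` tumor copies in
#' a sample of purity `p` (contaminating normal cells are diploid het), the
#' expected allele fraction is
#' \deqn{AF = (p m + (1-p)) / (p c + 2 (1-p)).}
#' At purity 1 this reduces to `m/c`; at `c = 2, m = 1` it is 0.5 for any
#' purity.
#'
#' @param m Copies carrying the variant allele.
#' @param c Total tumor copy number at the locus.
#' @param purity Tumor purity in (0, 1].
#' @return Expected allele fraction.
#' @export
expected_het_af <- function(m, c, purity = 1) {
  stopifnot(all(purity > 0), all(purity <= 1), all(m <= c))
  (purity * m + (1 - purity)) / (purity * c + 2 * (1 - purity))
}

# Best (high, low) haplotype copy split for one sample: for each candidate
# (a, b) with a + b = cn, a >= b, assign each AF to the nearer expected
# cluster and keep the split with minimal squared error.
fit_allele_split <- function(af, cn, purity) {
  cand <- tibble(a = seq.int(ceiling(cn / 2), cn), b = cn - seq.int(ceiling(cn / 2), cn))
  fits <- purrr::pmap(cand, function(a, b) {
    e_hi <- expected_het_af(a, cn, purity)
    e_lo <- expected_het_af(b, cn, purity)
    hi <- abs(af - e_hi) <= abs(af - e_lo)
    sse <- sum(pmin((af - e_hi)^2, (af - e_lo)^2))
    list(a = a, b = b, hi = hi, sse = sse)
  })
  fits[[which.min(purrr::map_dbl(fits, "sse"))]]
}

#' Infer paired allele-specific copy states from inherited het AFs
#'
#' Given the allele fractions of inherited heterozygous variants at one locus
#' in two samples, assigns each variant to the nearest expected-AF cluster
#' under the purity mixture model of [expected_het_af()], yielding each
#' sample's (count_A, count_B) parental-allele copy counts, and determines by
#' majority vote whether the amplified/major allele in sample 1 is the same
#' parental allele as in sample 2. Variants with AF in (0.4, 0.6) are
#' excluded from the vote when either sample is at LOH (uninformative under
#' noise). An ambiguous vote (fraction below `min_vote`) is an error rather
#' than a silent call.
#'
#' @param afs Tibble (or data frame) with columns `af_1`, `af_2`: per-variant
#'   allele fractions in the two samples; at least 10 variants.
#' @param cn_1,cn_2 Total copy number of the locus in each sample.
#' @param purity_1,purity_2 Tumor purities in (0, 1].
#' @param min_vote Minimum majority-vote fraction; default 0.9.
#' @return List with `state_1`, `state_2` (named vectors `c(count_A, count_B)`
#'   on a shared parental-allele labeling where allele A is the major allele
#'   of sample 1), `concordant` (`TRUE` when sample 1's major allele is the
#'   retained/major allele of sample 2, `NA` when a sample is balanced) and
#'   `vote_fraction`.
#' @export
infer_allele_state_pair <- function(afs, cn_1, cn_2, purity_1 = 1, purity_2 = 1,
                                    min_vote = 0.9) {
  stopifnot(all(c("af_1", "af_2") %in% names(afs)))
  if (nrow(afs) < 10) abort("need at least 10 inherited het variants at the locus")
  f1 <- fit_allele_split(afs$af_1, cn_1, purity_1)
  f2 <- fit_allele_split(afs$af_2, cn_2, purity_2)
  state_1 <- c(count_A = f1$a, count_B = f1$b)
  if (f1$a == f1$b || f2$a == f2$b) {
    # balanced state in one sample: haplotype identity unresolvable
    return(list(state_1 = state_1,
                state_2 = c(count_A = f2$a, count_B = f2$b),
                concordant = NA, vote_fraction = NA_real_))
  }
  voting <- rep(TRUE, nrow(afs))
  if (f1$b == 0 || f2$b == 0) {
    voting <- !(afs$af_1 > 0.4 & afs$af_1 < 0.6) &
      !(afs$af_2 > 0.4 & afs$af_2 < 0.6)
  }
  if (sum(voting) < 10) abort("fewer than 10 informative variants after LOH AF exclusion")
  same <- mean(f1$hi[voting] == f2$hi[voting])
  vote <- max(same, 1 - same)
  if (vote < min_vote) {
    abort(sprintf("ambiguous allele pairing: vote fraction %.2f < %.2f",
                  vote, min_vote))
  }
  concordant <- same >= 0.5
  state_2 <- if (concordant) c(count_A = f2$a, count_B = f2$b)
             else c(count_A = f2$b, count_B = f2$a)
  list(state_1 = state_1, state_2 = state_2,
       concordant = concordant, vote_fraction = vote)
}

#' Order two allele-specific copy states by ancestry
#'
#' State X can precede state Y when Y is reachable from X by copy-count
#' changes in which no parental allele returns from count zero (an allele
#' once lost cannot be regained). The check is symmetric; states reachable in
#' both directions (including X = Y) are `"equivalent"`, reachable in neither
#' `"incomparable"`.
#'
#' @param x,y Named vectors `c(count_A, count_B)` on a shared parental-allele
#'   labeling (see [infer_allele_state_pair()]).
#' @return One of `"precedes"`, `"follows"`, `"equivalent"`,
#'   `"incomparable"`.
#' @export
order_allele_states <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  if (any(is.na(x)) || any(is.na(y))) abort("unresolved allele state")
  xy <- !any(x == 0 & y > 0)   # no resurrection along x -> y
  yx <- !any(y == 0 & x > 0)
  if (xy && yx) "equivalent"
  else if (xy) "precedes"
  else if (yx) "follows"
  else "incomparable"
}
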