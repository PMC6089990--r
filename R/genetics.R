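#' Test tetrads against the monogenic 2:2 expectation
#'
#' A recessive trait controlled by a single nuclear gene segregates exactly
#' 2 resistant : 2 sensitive in every complete tetrad. This reports the
#' per-tetrad conformity, the overall conforming fraction, and the
#' probability of observing the data (all tetrads conforming or not) under
#' the monogenic model (where P(2:2) = 1) versus a two-gene independent
#' model, estimated by simulation.
#'
#' Under two unlinked genes with resistance requiring both mutant alleles,
#' tetrad types PD:NPD:T occur 1:1:4 and only parental ditypes (probability
#' 1/6) are 2:2.
#'
#' @param tetrads Data frame with columns `tetrad_id`, `s1`..`s4`, each
#'   spore phenotype `"resistant"` or `"sensitive"` (abbreviations `R`/`S`
#'   accepted).
#' @param n_sim Simulation replicates for the two-gene null.
#' @param seed Seed for the simulation.
#' @return List with `per_tetrad` (data frame), `fraction_conforming`,
#'   `n_tetrads`, `p_all_conforming_monogenic`,
#'   `p_all_conforming_two_gene` (simulated), and
#'   `p_two_gene_exact` (= (1/6)^n, the analytic value).
#' @export
tetrad_pattern_test <- function(tetrads, n_sim = 10000L, seed = 1L) {
  tetrads <- as.data.frame(tetrads)
  need <- c("tetrad_id", "s1", "s2", "s3", "s4")
  if (nrow(tetrads) == 0L) stop("need at least one tetrad")
  if (!all(need %in% names(tetrads))) {
    stop("tetrad table must have columns: ", paste(need, collapse = ", "))
  }
  norm_pheno <- function(x) {
    x <- tolower(as.character(x))
    x[x %in% c("r", "res", "resistant")] <- "resistant"
    x[x %in% c("s", "sen", "sensitive")] <- "sensitive"
    if (any(!x %in% c("resistant", "sensitive"))) {
      stop("malformed spore phenotype: ",
           paste(unique(x[!x %in% c("resistant", "sensitive")]), collapse = ", "))
    }
    x
  }
  spores <- vapply(c("s1", "s2", "s3", "s4"),
                   function(col) norm_pheno(tetrads[[col]]),
                   character(nrow(tetrads)))
  spores <- matrix(spores, nrow = nrow(tetrads))
  n_res <- rowSums(spores == "resistant")
  per <- data.frame(tetrad_id = tetrads$tetrad_id,
                    n_resistant = n_res,
                    n_sensitive = 4L - n_res,
                    conforms_2_2 = n_res == 2L)
  frac <- mean(per$conforms_2_2)
  n <- nrow(per)
  all_conform <- all(per$conforms_2_2)
  # two-gene independent null: P(2:2 tetrad) = P(parental ditype) = 1/6
  set.seed(seed)
  sims <- stats::rbinom(n_sim, n, 1 / 6)
  p_two_sim <- mean(sims == n)
  list(per_tetrad = per,
       n_tetrads = n,
       fraction_conforming = frac,
       p_all_conforming_monogenic = if (all_conform) 1.0 else 0.0,
       p_all_conforming_two_gene = p_two_sim,
       p_two_gene_exact = (1 / 6)^n)
}

#' Exact two-sided binomial test for spore segregation
#'
#' Tests observed resistant/sensitive spore counts against a null
#' segregation ratio (1:1 by default, the monogenic random-spore
#' expectation). The two-sided p-value is the exact sum of the
#' probabilities of all outcomes no more likely than the observed one.
#'
#' @param n_total Total spores scored.
#' @param n_resistant Resistant spores.
#' @param p0 Null probability of the resistant phenotype.
#' @return The two-sided p-value. The full `htest` object is attached as
#'   attribute `"test"`.
#' @export
segregation_binomial_test <- function(n_total, n_resistant, p0 = 0.5) {
  stopifnot(n_total >= 1L, n_resistant >= 0L, n_resistant <= n_total)
  ht <- stats::binom.test(n_resistant, n_total, p = p0,
                          alternative = "two.sided")
  structure(unname(ht$p.value), test = ht)
}

#' Reconstruct spore counts from printed percentages
#'
#' Published segregation data often report only percentages of a stated
#' total. This returns the integer count candidates (floor and ceiling of
#' `n_total * pct / 100`), flagging whether the reconstruction is exact.
#'
#' @param n_total Total spores.
#' @param pct_resistant Printed percentage of resistant spores.
#' @return Data frame of candidate `n_resistant` values with `exact` flag.
#' @export
reconstruct_spore_counts <- function(n_total, pct_resistant) {
  k <- n_total * pct_resistant / 100
  if (abs(k - round(k)) < 1e-9) {
    data.frame(n_resistant = as.integer(round(k)), exact = TRUE)
  } else {
    data.frame(n_resistant = as.integer(c(floor(k), ceiling(k))),
               exact = FALSE)
  }
}

#' Simulate a cross between a mutant and a wild-type strain
#'
#' In-silico counterpart of sporulating a heterozygous diploid and scoring
#' progeny. Under the monogenic model every tetrad is exactly 2:2 and bulk
#' spores are Binomial(n, 1/2) resistant; under two independent genes
#' (resistance requiring both mutant alleles) tetrad types PD:NPD:T are
#' drawn 1:1:4 (2:2, 0:4, 1:3 resistant) and bulk spores are
#' Binomial(n, 1/4).
#'
#' @param n_spores Number of random spores to score (or `NULL`).
#' @param n_tetrads Number of tetrads to dissect (or `NULL`).
#' @param model `"monogenic"` or `"two-gene-independent"`.
#' @param seed Mandatory seed.
#' @return List with `spores` (data frame `n_total`/`n_resistant`/
#'   `n_sensitive`) and/or `tetrads` (data frame `tetrad_id`, `s1`..`s4`).
#' @export
simulate_cross <- function(n_spores = NULL, n_tetrads = NULL,
                           model = c("monogenic", "two-gene-independent"),
                           seed) {
  model <- match.arg(model)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  out <- list(model = model, seed = seed)
  p_res <- if (model == "monogenic") 0.5 else 0.25
  if (!is.null(n_spores)) {
    k <- stats::rbinom(1L, n_spores, p_res)
    out$spores <- data.frame(n_total = n_spores, n_resistant = k,
                             n_sensitive = n_spores - k)
  }
  if (!is.null(n_tetrads)) {
    mk_tetrad <- function(n_res) {
      sample(c(rep("resistant", n_res), rep("sensitive", 4L - n_res)))
    }
    rows <- lapply(seq_len(n_tetrads), function(i) {
      n_res <- if (model == "monogenic") 2L else {
        # PD:NPD:T = 1:1:4 -> resistant spores 2, 0, 1
        c(2L, 0L, 1L)[sample.int(3L, 1L, prob = c(1, 1, 4))]
      }
      s <- mk_tetrad(n_res)
      data.frame(tetrad_id = paste0("T", i), s1 = s[1L], s2 = s[2L],
                 s3 = s[3L], s4 = s[4L])
    })
    out$tetrads <- do.call(rbind, rows)
  }
  out
}

#' Read tetrad phenotypes from a TSV file
#'
#' @param path TSV with columns `tetrad_id`, `s1`..`s4`.
#' @return Data frame suitable for [tetrad_pattern_test()].
#' @export
read_tetrads <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tetrad_id", "s1", "s2", "s3", "s4")
  if (!all(need %in% names(tab))) {
    stop("tetrad file needs columns: ", paste(need, collapse = ", "))
  }
  tab[, need]
}
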