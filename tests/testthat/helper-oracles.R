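# Independent brute-force oracles shared across test files. These
# re-derive expected results from first principles (enumeration, closed
# forms) and never call the implementation paths they check.

# Enumerate all transmissions consistent with a trio; derive the origin
# category by brute force. Missing parents range over every genotype.
oraclePofo <- function(child, mother, father) {
  alleles <- function(g) strsplit(g, "")[[1]]
  genos <- c("TT", "TC", "CC")
  mothers <- if (is.na(mother)) genos else mother
  fathers <- if (is.na(father)) genos else father
  childA <- sort(alleles(child))

  # all (maternal transmitted, paternal transmitted) pairs matching the child
  consistentPairs <- function(m, f) {
    out <- list()
    for (mt in alleles(m)) for (ft in alleles(f))
      if (identical(sort(c(mt, ft)), childA))
        out[[length(out) + 1L]] <- c(mt, ft)
    unique(out)
  }

  anyConsistent <- FALSE
  for (m in mothers) for (f in fathers)
    if (length(consistentPairs(m, f))) anyConsistent <- TRUE
  if (!anyConsistent) return("mendelian_error")
  if (child != "TC") return("not_applicable")

  # possible origins of the C allele over all candidate parent genotypes
  origins <- character(0)
  for (m in mothers) for (f in fathers)
    for (pr in consistentPairs(m, f))
      origins <- union(origins, if (pr[2] == "C") "paternal" else "maternal")
  if (length(origins) == 1L) return(origins)
  if (!is.na(mother) && !is.na(father)) "ambiguous" else "unknown"
}

# Benjamini-Hochberg step-up from the definition: sort, scale by m/i,
# enforce monotonicity from the largest down, cap at 1, restore order.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# DerSimonian-Laird pooling written out step by step.
oracleDL <- function(est, se) {
  k <- length(est)
  w <- 1 / se^2
  fixed <- sum(w * est) / sum(w)
  Q <- sum(w * (est - fixed)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wStar <- 1 / (se^2 + tau2)
  list(estimate = sum(wStar * est) / sum(wStar),
       se = 1 / sqrt(sum(wStar)), Q = Q, tau2 = tau2)
}

# Expected usage label from the assignment rules, spelled out per case.
oracleUsage <- function(status, genotype) {
  if (!status %in% c("imprinted", "intermediate", "non_methylated"))
    return("excluded")
  if (status == "intermediate") return("excluded")
  if (status == "imprinted" && genotype == "TC") return("excluded")
  if (status == "imprinted" && genotype == "TT") return("control")
  "elevated"
}

# Small beta matrix with controllable values.
makeBetaMatrix <- function(values, probes = nc886Probes()) {
  n <- length(values)
  m <- matrix(rep(values, length(probes)), nrow = n,
              dimnames = list(sprintf("S%03d", seq_len(n)), probes))
  m
}
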