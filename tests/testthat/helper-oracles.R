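# Independent oracles used across the suite. These deliberately avoid the
# package's convolution code paths.

# All multisets of `n` items over `k` isotope slots.
.multinomial_vectors <- function(n, k) {
  if (k == 1) return(matrix(n, nrow = 1))
  out <- NULL
  for (first in 0:n) {
    rest <- .multinomial_vectors(n - first, k - 1)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

# Exhaustive isotopologue enumeration for small compositions: returns a
# data.frame(mass, abundance) aggregated by nominal shift, normalized.
oracle_pattern_exhaustive <- function(cmp, prune = 1e-15) {
  iso <- macromet::element_table()$isotopes
  per_el <- list()
  for (el in names(cmp)) {
    rows <- iso[iso$element == el, ]
    vecs <- .multinomial_vectors(unclass(cmp)[[el]], nrow(rows))
    lw <- lgamma(unclass(cmp)[[el]] + 1)
    ab <- apply(vecs, 1, function(v)
      exp(lw - sum(lgamma(v + 1)) + sum(v * log(rows$abundance))))
    mass <- as.numeric(vecs %*% rows$mass)
    per_el[[el]] <- data.frame(mass = mass, ab = ab)
  }
  cur <- data.frame(mass = 0, ab = 1)
  for (el in names(per_el)) {
    nxt <- expand.grid(i = seq_len(nrow(cur)), j = seq_len(nrow(per_el[[el]])))
    cur <- data.frame(mass = cur$mass[nxt$i] + per_el[[el]]$mass[nxt$j],
                      ab = cur$ab[nxt$i] * per_el[[el]]$ab[nxt$j])
    cur <- cur[cur$ab > prune, ]
  }
  mono <- macromet::monoisotopic_mass(cmp)
  k <- round(cur$mass - mono)
  ab <- tapply(cur$ab, k, sum)
  msum <- tapply(cur$ab * cur$mass, k, sum)
  out <- data.frame(k = as.integer(names(ab)),
                    mass = as.numeric(msum / ab),
                    abundance = as.numeric(ab))
  out <- out[order(out$k), ]
  out$abundance <- out$abundance / sum(out$abundance)
  rownames(out) <- NULL
  out
}

# Abundance-only nominal-bin distribution by sequential one-atom-at-a-time
# polynomial multiplication (no squaring, no mass tracking).
oracle_pattern_sequential <- function(cmp, prune = 1e-12) {
  iso <- macromet::element_table()$isotopes
  dist <- 1
  for (el in names(cmp)) {
    rows <- iso[iso$element == el, ]
    shifts <- round(rows$mass - rows$mass[1])
    atom <- numeric(max(shifts) + 1)
    for (r in seq_len(nrow(rows)))
      atom[shifts[r] + 1] <- atom[shifts[r] + 1] + rows$abundance[r]
    for (rep in seq_len(unclass(cmp)[[el]])) {
      new <- numeric(length(dist) + length(atom) - 1)
      for (i in seq_along(dist)) {
        if (dist[i] == 0) next
        idx <- i:(i + length(atom) - 1)
        new[idx] <- new[idx] + dist[i] * atom
      }
      new[new < prune * max(new)] <- 0
      dist <- new
    }
  }
  dist / sum(dist)
}

# Random peptide structure from the proteinogenic registry.
random_peptide <- function(n, registry = macromet::default_registry()) {
  codes <- c("Gly", "Ala", "Ser", "Pro", "Val", "Thr", "Leu", "Ile", "Asn",
             "Asp", "Gln", "Glu", "Lys", "Met", "His", "Phe", "Arg", "Tyr",
             "Trp", "Cys")
  seq <- paste0("H-", paste(sample(codes, n, replace = TRUE), collapse = "-"),
                "-OH")
  macromet::parse_sequence(seq, registry)
}
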