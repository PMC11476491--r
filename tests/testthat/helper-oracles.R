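# Independent straight-line oracles used across tests. These deliberately
# re-derive each quantity from first principles (loops, enumeration) and
# share no code with the package implementation.

# Verbatim transcription of the three-level call-back rules, one gene at a
# time, no vectorization.
oracleCallback <- function(m_lfc, m_fdr, t_lfc, t_fdr) {
  n <- length(m_lfc)
  level <- character(n)
  direction <- character(n)
  for (i in seq_len(n)) {
    lm <- m_lfc[i]; fm <- m_fdr[i]; lt <- t_lfc[i]; ft <- t_fdr[i]
    opposite <- (lm < 0 && lt > 0) || (lm > 0 && lt < 0)
    if (abs(lm) > 0.5 && fm < 0.05 && abs(lt) > 0.5 && ft < 0.05 &&
        opposite) {
      level[i] <- "1"
      direction[i] <- if (lm < 0) "up-called-back" else "down-called-back"
    } else if (abs(lm) > 0.1 && fm < 0.05 && abs(lt) > 0.1 && ft < 0.05 &&
               opposite) {
      level[i] <- "2"
      direction[i] <- if (lm < 0) "up-called-back" else "down-called-back"
    } else if (fm > 0.05 && abs(lt) > 0.1 && ft < 0.05) {
      level[i] <- "3"
      direction[i] <- if (lt > 0) "treatment-up" else "treatment-down"
    } else {
      level[i] <- "none"
      direction[i] <- "none"
    }
  }
  list(level = level, direction = direction)
}

# Textbook BH step-up: adjusted_(i) = min over j >= i of m * p_(j) / j,
# capped at 1, mapped back to the input order.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws.
oracleHyperEnum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are "in the set"
  mean(hits >= k)
}

# Exclusive intersection sizes by per-element membership enumeration.
oracleUpset <- function(lists) {
  universe <- unique(unlist(lists))
  sizes <- list()
  for (g in universe) {
    key <- paste(vapply(lists, function(s) g %in% s, TRUE), collapse = "")
    sizes[[key]] <- c(sizes[[key]], g)
  }
  lapply(sizes, length)
}

# Small deterministic experiment from explicit per-arm counts.
makeIre <- function(counts_by_arm, geneLengths = NULL) {
  mats <- lapply(names(counts_by_arm), function(a) {
    m <- counts_by_arm[[a]]
    colnames(m) <- paste(a, seq_len(ncol(m)), sep = "_")
    m
  })
  cnt <- do.call(cbind, mats)
  if (is.null(rownames(cnt))) {
    rownames(cnt) <- paste0("g", seq_len(nrow(cnt)))
  }
  arm <- rep(names(counts_by_arm),
             vapply(counts_by_arm, ncol, 0L))
  InjuryRescueExperiment(cnt, arms = arm, geneLengths = geneLengths)
}

# DEResults-shaped data.frame for classifier tests.
deTable <- function(gene_id, log2fc, fdr) {
  data.frame(gene_id = gene_id, base_mean = 100, log2fc = log2fc,
             dispersion = 0.05, p_value = fdr, fdr = fdr,
             stringsAsFactors = FALSE)
}
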