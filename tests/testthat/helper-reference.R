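# Reference per-variable descriptive statistics (mean, sample sd, min, max)
# of the bundled 19-subject cohort, recomputed independently from the raw
# table. Two cells of the originally published summary table are typos and
# are stored here at their recomputed values: the DG maximum (3, printed as
# 1) and the BAN standard deviation (1.27, printed as 1.17).
referenceStats <- function() {
  list(
    "Numero Risposte" = c(10.32, 3.83, 4, 18), G = c(5.42, 2.81, 1, 13),
    D = c(4.58, 3.06, 0, 10), Dd = c(0.11, 0.32, 0, 1),
    DG = c(0.21, 0.71, 0, 3),
    F = c(8.53, 4.14, 2, 16), "F+" = c(5.63, 3.20, 1, 12),
    "F-" = c(2.89, 2.21, 0, 8),
    M = c(0.74, 0.73, 0, 3), FM = c(0.74, 1.24, 0, 4), m = c(0.05, 0.23, 0, 1),
    CF = c(0.05, 0.23, 0, 1), Fcho = c(0.11, 0.32, 0, 1),
    CHO = c(0.05, 0.23, 0, 1),
    BAN = c(2.21, 1.27, 0, 4), ORIG = c(0.11, 0.32, 0, 1),
    A = c(5.84, 2.59, 0, 10), Ad = c(0.47, 1.02, 0, 4), U = c(1.26, 1.48, 0, 5),
    "(u)" = c(0.11, 0.32, 0, 1), Ud = c(0.37, 0.83, 0, 3),
    Obj = c(0.95, 1.31, 0, 4),
    Cibo = c(0.16, 0.37, 0, 1), Nat = c(0.11, 0.32, 0, 1),
    Bot = c(0.58, 0.96, 0, 3),
    Anat = c(0.32, 0.75, 0, 3), Fumo = c(0.05, 0.23, 0, 1),
    Cartoon = c(0.11, 0.32, 0, 1),
    Art = c(0.11, 0.32, 0, 1), IR = c(3.58, 1.80, 0, 6),
    "TRI I" = c(1.74, 0.99, 1, 3), "TRI II" = c(2.16, 0.96, 1, 3),
    Perseverazioni = c(0.37, 0.50, 0, 1), Inadeguatezza = c(0.21, 0.42, 0, 1),
    Insicurezza = c(0.26, 0.45, 0, 1), Stereotipie = c(0.05, 0.23, 0, 1),
    Rifiuti = c(0.63, 0.50, 0, 1), Confabulazione = c(0.21, 0.42, 0, 1),
    Astrazione = c(0.05, 0.23, 0, 1), Contaminazione = c(0.05, 0.23, 0, 1),
    "Diff. Denominazione" = c(0.05, 0.23, 0, 1),
    Autoriferimento = c(0.11, 0.32, 0, 1),
    Devitalizzazione = c(0.11, 0.32, 0, 1), Sensazione = c(0.11, 0.32, 0, 1)
  )
}

# Brute-force minimum spanning tree via Pruefer-sequence enumeration of all
# labelled spanning trees on n nodes (n <= 7). Returns the minimum total
# weight.
bruteForceMSTWeight <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 2, n <= 7)
  if (n == 2) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (s in seq_len(nrow(seqs))) {
    prue <- seqs[s, ]
    degree <- rep(1L, n)
    for (p in prue) degree[p] <- degree[p] + 1L
    w <- 0
    pr <- prue
    deg <- degree
    for (p in pr) {
      leaf <- which(deg == 1L)[1]
      w <- w + d[leaf, p]
      deg[leaf] <- 0L
      deg[p] <- deg[p] - 1L
    }
    left <- which(deg == 1L)
    w <- w + d[left[1], left[2]]
    if (w < best) best <- w
  }
  best
}

# Random symmetric distance matrix with named nodes.
randomDistanceMatrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 1)
  d <- d + t(d)
  dimnames(d) <- list(paste0("N", seq_len(n)), paste0("N", seq_len(n)))
  d
}

# Total weight (1 - strength summed) of a VariableGraph's edges under a
# distance matrix.
graphDistanceWeight <- function(g, d) {
  e <- graphEdges(g)
  sum(vapply(seq_len(nrow(e)),
             function(k) d[e$u[k], e$v[k]], numeric(1)))
}

# A small deterministic toy cohort with a clean group effect, for cheap
# end-to-end checks.
toyCohort <- function() {
  m <- rbind(
    matrix(c(2, 5, 0, 1,
             3, 4, 1, 0,
             2, 6, 0, 0,
             1, 5, 1, 1), 4, 4, byrow = TRUE),
    matrix(c(8, 1, 3, 0,
             9, 2, 4, 1,
             7, 1, 3, 0,
             8, 0, 2, 1,
             9, 1, 4, 0), 5, 4, byrow = TRUE))
  colnames(m) <- c("W", "X", "Y", "Z")
  rownames(m) <- c(paste("AD", 1:4), paste("INPH", 1:5))
  RorschachCohort(m, group = rep(c("AD", "INPH"), c(4, 5)))
}
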