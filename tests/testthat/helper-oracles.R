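## Independent brute-force oracles used across tests. These never call the
## package's analytic solvers.

## BMC by dense log-grid evaluation of a curve function, optionally refined by
## plain bisection on the first crossed threshold.
gridBmc <- function(f, bmr, direction, maxConc, minConc = maxConc * 1e-7,
                    nGrid = 1e6, refine = FALSE) {
  xs <- seq(log10(minConc), log10(maxConc), length.out = nGrid)
  ys <- f(10^xs)
  lowT <- 100 - bmr; highT <- 100 + bmr
  adverse <- switch(direction,
    decrease_adverse = ys <= lowT,
    increase_adverse = ys >= highT,
    both = ys <= lowT | ys >= highT)
  i <- which(adverse)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1 || !refine) return(10^xs[i])
  thr <- if (direction == "decrease_adverse") lowT
         else if (direction == "increase_adverse") highT
         else if (ys[i] >= highT) highT else lowT
  sgn <- sign(f(10^xs[i]) - thr)
  a <- xs[i - 1]; b <- xs[i]
  for (k in 1:200) {
    m <- (a + b) / 2
    if (sign(f(10^m) - thr) == sgn) b <- m else a <- m
  }
  10^((a + b) / 2)
}

## Direct interval-arithmetic overlap fraction (DNT denominator).
directOverlap <- function(ciDnt, ciRef) {
  inter <- max(0, min(ciDnt[2], ciRef[2]) - max(ciDnt[1], ciRef[1]))
  inter / (ciDnt[2] - ciDnt[1])
}

## Brute-force transitive closure of 3-fold range overlap: breadth-first
## search on the pairwise overlap graph of [b/3, 3b] intervals.
bruteTieGroups <- function(bmcs, fold = 3) {
  n <- length(bmcs)
  lo <- bmcs / fold; hi <- bmcs * fold
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- lo[i] <= hi[j] && lo[j] <= hi[i]
  comp <- rep(NA_integer_, n); k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

## Intended-vs-recovered label match count for a pipeline run on a battery.
labelRecovery <- function(bundle) {
  m <- merge(bundle@hitTable, bundle@groundTruth,
             by = c("compound", "endpoint"))
  intended <- ifelse(m$intended_label == "negative", "no_hit",
                     m$intended_label)
  sum(intended == m$classification)
}
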