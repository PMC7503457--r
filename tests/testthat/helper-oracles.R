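# Independent oracles used across tests.

# Exhaustive-enumeration oracle for the shared-miRNA overlap test: fix the
# lncRNA's miRNA set as {1..L}, enumerate every M-subset of {1..N}, and count
# the fraction with overlap >= x. Exact for the small universes it is used on.
hyper_oracle <- function(L, M, x, N) {
  if (x == 0) return(1)
  if (M == 0) return(0)
  subsets <- utils::combn(N, M)
  overlaps <- colSums(subsets <= L)
  mean(overlaps >= x)
}

# Hand product-limit (Kaplan-Meier) estimator for one group.
km_oracle <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  out <- data.frame(time = unique(time), surv = NA_real_)
  s <- 1
  for (i in seq_len(nrow(out))) {
    t <- out$time[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

triplet_key <- function(df) paste(df$lnc_id, df$mir_id, df$mrna_id)
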