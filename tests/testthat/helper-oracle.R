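# Literal first-come-first-served reference assignment: walk patients in row
# order, each takes the cheapest column that still has capacity (ties ->
# lowest column index). Deliberately naive; used as the independent oracle for
# the compiled greedy implementation.
fcfs_reference <- function(cost, slots) {
  rem <- as.integer(slots)
  out <- rep(NA_integer_, nrow(cost))
  for (i in seq_len(nrow(cost))) {
    open <- which(rem > 0L)
    if (length(open) == 0L) next
    j <- open[which.min(cost[i, open])]
    out[i] <- j
    rem[j] <- rem[j] - 1L
  }
  out
}

random_cost_instance <- function(n_max = 6, k_max = 4, slot_max = 3) {
  n <- sample(0:n_max, 1)
  k <- sample(1:k_max, 1)
  list(
    cost = matrix(round(runif(n * k, 0, 100), 1), n, k),
    slots = sample(0:slot_max, k, replace = TRUE)
  )
}
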