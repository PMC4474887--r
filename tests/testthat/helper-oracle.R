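# Independent reaction-channel oracle: the 25 reaction channels written
# down one by one as (rate, stoichiometry) pairs and summed per species.
# Deliberately structured nothing like the packaged right-hand side.

oracle_channels <- function(p) {
  e <- function(...) {
    v <- numeric(13)
    args <- list(...)
    for (j in seq(1, length(args), by = 2)) v[args[[j]]] <- args[[j + 1]]
    v
  }
  list(
    # cell-cycle block
    list(rate = function(x) p$k1,                                st = e(1, +1)),
    list(rate = function(x) p$k2 * x[1] * x[3] / (p$k3 + x[1]),  st = e(1, -1)),
    list(rate = function(x) p$k4 * x[1],                         st = e(1, -1)),
    list(rate = function(x) {
      k5 <- p$k14 * x[1] / (p$k13 + x[1])
      k5 * (1 - x[2]) / (p$k6 + (1 - x[2]))
    }, st = e(2, +1)),
    list(rate = function(x) p$k7 * x[2] / (p$k8 + x[2]),         st = e(2, -1)),
    list(rate = function(x) {
      k9 <- p$k15 * x[2]
      k9 * (1 - x[3]) / (p$k10 + (1 - x[3]))
    }, st = e(3, +1)),
    list(rate = function(x) p$k11 * x[3] / (p$k12 + x[3]),       st = e(3, -1)),
    # p53 - Mdm2 core
    list(rate = function(x) p$k16,                               st = e(4, +1)),
    list(rate = function(x) p$k17 * x[4] * x[5], st = e(4, -1, 5, -1, 6, +1)),
    list(rate = function(x) p$k18 * x[6],        st = e(4, +1, 5, +1, 6, -1)),
    list(rate = function(x) p$k19 * x[6],        st = e(6, -1, 5, +1)),
    list(rate = function(x) p$k20 * x[4],        st = e(7, +1)),
    list(rate = function(x) p$k21 * x[7],        st = e(7, -1)),
    list(rate = function(x) p$k22 * x[7],        st = e(5, +1)),
    list(rate = function(x) p$k23 * x[5],        st = e(5, -1)),
    # damage / ARF branch
    list(rate = function(x) p$k24 * x[10],       st = e(10, -1, 11, +1)),
    list(rate = function(x) p$k25 * x[11],       st = e(11, -1)),
    list(rate = function(x) p$k26 * x[11],       st = e(8, +1)),
    list(rate = function(x) p$k27 * x[5] * x[8], st = e(5, -1, 8, -1, 9, +1)),
    list(rate = function(x) p$k28 * x[8],        st = e(8, -1)),
    list(rate = function(x) p$k29 * x[9],        st = e(9, -1, 8, +1)),
    # p21 / MPF coupling
    list(rate = function(x) p$k30 * x[4],            st = e(12, +1)),
    list(rate = function(x) p$k31 * x[2] * x[12],
         st = e(2, -1, 12, -1, 13, +1)),
    list(rate = function(x) p$k32 * x[13],           st = e(13, -1, 12, +1)),
    list(rate = function(x) p$k33 * x[12],           st = e(12, -1))
  )
}

oracle_rhs <- function(state, params) {
  chans <- oracle_channels(params)
  d <- numeric(13)
  for (ch in chans) d <- d + ch$rate(state) * ch$st
  d
}

# Random strictly positive state with valid activation fractions.
random_state <- function() {
  x <- runif(13, 0.01, 5)
  x[2] <- runif(1, 0.01, 0.99)
  x[3] <- runif(1, 0.01, 0.99)
  x
}
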