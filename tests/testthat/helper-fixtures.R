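# Small seeded fixtures shared across the suite. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# a compact two-domain, two-class cohort (fast to train on)
smallBroadConfig <- function(seed = 1L, shift = domainShiftSpec(),
                             missingRate = 0, effect = 3) {
  syntheticConfig(
    counts = data.frame(
      domain = c("mouse", "mouse", "human", "human"),
      class = c("excitatory", "inhibitory", "excitatory", "inhibitory"),
      n = c(150L, 150L, 50L, 50L)),
    dFeatures = 12L,
    informativeSets = list(excitatory = 0:2, inhibitory = 3:5),
    classEffectSize = effect, shift = shift, missingRate = missingRate,
    seed = seed)
}

smallBroadSplit <- function(seed = 1L, shift = domainShiftSpec(), ...) {
  co <- generateCohort(smallBroadConfig(seed = seed, shift = shift, ...))
  suppressMessages(normalizeSplit(
    splitData(co$table, fractions = c(0.6, 0.2, 0.2), seed = seed)))
}

# a compact five-class mouse cohort for gated-classifier tests
smallSubclassConfig <- function(seed = 1L, effect = 3) {
  sets <- lapply(0:4, function(k) (2L * k):(2L * k + 1L))
  names(sets) <- c("Glutamatergic", "Pvalb", "Htr3a+|Vip-", "Sst", "Vip")
  syntheticConfig(
    counts = data.frame(domain = "mouse",
                        class = names(sets),
                        n = c(120L, 60L, 60L, 60L, 60L)),
    dFeatures = 14L, informativeSets = sets, classEffectSize = effect,
    seed = seed)
}

smallSubclassSplit <- function(seed = 1L, ...) {
  co <- generateCohort(smallSubclassConfig(seed = seed, ...))
  suppressMessages(normalizeSplit(
    splitData(co$table, fractions = c(0.7, 0.1, 0.2),
              stratifyOn = "subclass_label", seed = seed)))
}

# a tiny smooth-activation DANN for finite-difference work (<= 50 parameters)
tinyDANNModel <- function(seed = 7L) {
  cfg <- dannConfig(hidden = 3L, headHidden = integer(0),
                    activations = "swish", seed = seed)
  set.seed(seed)
  neurotype:::.newDANNModel(cfg, 2L)
}

tinyBatch <- function(n = 6L, seed = 11L) {
  set.seed(seed)
  list(x = matrix(rnorm(n * 2L), n, 2L),
       y = sample(0:1, n, replace = TRUE),
       d = sample(0:1, n, replace = TRUE))
}

# flatten every parameter of a DANN model into one numeric vector
dannParamVector <- function(model) {
  unlist(c(neurotype:::.netParams(model@extractor),
           neurotype:::.netParams(model@labelHead),
           neurotype:::.netParams(model@domainHead)))
}

# write a flat parameter vector back into a DANN model (FD oracle support)
dannSetParamVector <- function(model, vec) {
  at <- 0L
  fill <- function(net) {
    p <- neurotype:::.netParams(net)
    for (i in seq_along(p)) {
      k <- length(p[[i]])
      p[[i]][] <- vec[at + seq_len(k)]
      at <<- at + k
    }
    neurotype:::.setNetParams(net, p)
  }
  model@extractor <- fill(model@extractor)
  model@labelHead <- fill(model@labelHead)
  model@domainHead <- fill(model@domainHead)
  model
}

# central finite differences of a scalar function over a parameter vector
finiteDiff <- function(fun, p0, h = 1e-5) {
  vapply(seq_along(p0), function(i) {
    up <- p0; up[i] <- up[i] + h
    dn <- p0; dn[i] <- dn[i] - h
    (fun(up) - fun(dn)) / (2 * h)
  }, 0)
}
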