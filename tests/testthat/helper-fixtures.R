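# shared fixtures, all generated in code

# reference set engineered so that C = S implies C = 1.5 * B:
# closed-form toy where Pi = 1, Igeo = 0, PEI = Tr, TEI = sum(Tr) = 58
toy_refs <- function() {
  B <- c(Cr = 40, Ni = 20, Cu = 30, Zn = 200, As = 10, Cd = 0.4, Pb = 20)
  reference_set(screening = 1.5 * B, background = B,
                toxicity = c(Cr = 2, Ni = 5, Cu = 5, Zn = 1, As = 10,
                             Cd = 30, Pb = 5),
                name = "toy")
}

toy_samples <- function(refs = toy_refs()) {
  m <- hm_metals()
  as_sample_table(data.frame(
    site = rep(c("A", "B"), each = 7),
    layer = "APMS", metal = rep(m, 2),
    conc_mg_kg = rep(unname(refs$screening[m]), 2)))
}

# random positive sample table, n sites in one layer
random_samples <- function(n, seed = 1) {
  set.seed(seed)
  m <- hm_metals()
  as_sample_table(data.frame(
    site = rep(paste0("S", seq_len(n)), each = 7),
    layer = "APMS", metal = rep(m, n),
    conc_mg_kg = stats::rlnorm(7 * n, meanlog = 2, sdlog = 0.7)))
}

# layer-mean and layer-SD targets as named vectors
target_means <- function(layer) {
  tg <- profile_targets()
  stats::setNames(tg$mean[tg$layer == layer], tg$metal[tg$layer == layer])
}
target_sds <- function(layer) {
  tg <- profile_targets()
  stats::setNames(tg$sd[tg$layer == layer], tg$metal[tg$layer == layer])
}

# published per-layer mean single-metal risk indices and geoaccumulation
# indices used as cross-checks of the shipped constants
published_pei_means <- function(layer) {
  if (layer == "APMS")
    c(Cr = 0.437, Ni = 5.417, Cu = 3.323, Zn = 0.965, As = 6.293,
      Cd = 56.45, Pb = 1.012)
  else
    c(Cr = 0.360, Ni = 5.098, Cu = 2.273, Zn = 0.692, As = 5.730,
      Cd = 49.94, Pb = 0.913)
}
published_igeo_means <- function(layer) {
  if (layer == "APMS")
    c(Cr = -0.830, Ni = 2.183, Cu = 0.982, Zn = 1.622, As = -0.136,
      Cd = 3.301, Pb = 0.186)
  else
    c(Cr = -1.107, Ni = 2.101, Cu = 0.549, Zn = 1.183, As = -0.286,
      Cd = 3.116, Pb = 0.033)
}
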