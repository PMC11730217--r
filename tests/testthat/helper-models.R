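## Shared fixtures, all built in code.  Models are cached per session
## because the scaffold + tail build is deterministic.

.modelCache <- new.env(parent = emptyenv())

cachedModel <- function(variant = "E") {
  key <- paste0("model_", variant)
  if (!exists(key, envir = .modelCache))
    assign(key, appendExtendedTail(makeScaffold(), makeVariant(variant)),
           envir = .modelCache)
  get(key, envir = .modelCache)
}

cachedIodinated <- function(variant = "E") {
  key <- paste0("dit_", variant)
  if (!exists(key, envir = .modelCache))
    assign(key,
           iodinateTyrosine(iodinateTyrosine(cachedModel(variant), 341L),
                            375L),
           envir = .modelCache)
  get(key, envir = .modelCache)
}

## n free (bond-less) atoms in a box, for brute-force pair-energy oracles.
freeAtoms <- function(n, seed = 1, elements = c("C", "N", "O"),
                      box = 8) {
  set.seed(seed)
  proteinStructure(data.frame(
    element = sample(elements, n, replace = TRUE),
    name = paste0("X", seq_len(n)),
    resname = "UNK", resid = seq_len(n), chain = "A",
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box)))
}

## Hand-made ensemble whose only mobile atom is the acceptor hydroxyl
## oxygen, placed at prescribed distances from the donor C-beta.
syntheticEnsemble <- function(distances, energies = rep(0, length(distances)),
                              variant = "E", condition = "Y_distal") {
  model <- cachedModel(variant)
  iOH <- atomIndex(model, 375L, "OH")
  cb <- atomXYZ(model, 341L, "CB")
  dir <- iodosite:::unitv(atomXYZ(model, 375L, "OH") - cb)
  frames <- lapply(distances, function(d)
    matrix(cb + d * dir, nrow = 1L, ncol = 3L))
  new("ConformerEnsemble", structure = model, mobile = iOH,
      frames = frames, condition = condition, seed = 0L,
      energies = energies, acceptanceRate = 1)
}

quickEnsemble <- function(variant = "E", nSteps = 400L, seed = 1L, ...) {
  sampleEnsemble(cachedModel(variant), "Y_distal",
                 samplerConfig(nSteps = nSteps, stride = 10L, seed = seed,
                               ...))
}
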