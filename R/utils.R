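# Internal helpers.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Small deterministic sub-seed derivation (kept below 2^31).
derive_seed <- function(master, block, index = 0L) {
  (as.numeric(master) * 1009 + as.numeric(block) * 97003 +
     as.numeric(index) * 101) %% 2147483647
}

# Stack a list of surface_maps sharing a mesh/mask into a V x n matrix.
stack_maps <- function(maps) {
  if (is.matrix(maps)) return(maps)
  if (inherits(maps, "surface_map")) maps <- list(maps)
  vapply(maps, function(m) m$values, numeric(length(maps[[1]]$values)))
}

shared_mask <- function(maps) {
  if (inherits(maps, "surface_map")) return(maps$mask)
  m <- maps[[1]]$mask
  for (x in maps[-1]) {
    if (!identical(x$mask, m)) stop("maps do not share a mask")
  }
  m
}
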