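# Seeding helpers: all randomness flows from one root seed via named
# substreams so components are independently reproducible.  The derived seed
# stays below 2^31 (R integers are 32-bit).

.subseed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

.with_subseed <- function(seed, label, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(.subseed(seed, label))
  expr
}
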