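# Shared fixtures. Small objects are rebuilt per call; the full default
# synthetic cohort and its signature discovery (used by the closed-loop
# acceptance checks) are computed once per session and cached.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, builder(), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

## tiny clinical table: half recurred with short times
tiny_clinical <- function(n = 20, seed = 1) {
  withr_seed(seed)
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             dfs_time = round(c(rexp(n %/% 2, 1 / 20), rexp(n - n %/% 2, 1 / 80)), 2),
             dfs_event = rep(c(1L, 0L), c(n %/% 2, n - n %/% 2)),
             er_status = "positive")
}

## set.seed without leaking into other tests (testthat runs each file fresh,
## but keep it tidy anyway)
withr_seed <- function(seed) set.seed(seed)

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

## The default-condition synthetic study: cohort, netMatrix, discovery, CSS.
default_study <- function() {
  cached("default_study", function() {
    ds <- simulate_dataset(sim_config(), seed = 101)
    fg <- merge_functional_genes(ds$cohort$annotations)
    clones <- suppressWarnings(build_founding_clones(ds$cohort$mutations, fg))
    nm <- build_netmatrix(suppressWarnings(
      propagate_cohort(ds$network$edges, clones)))
    cl <- ds$cohort$clinical
    disc <- suppressWarnings(
      discover_signatures(nm, cl, ds$evidence$hallmarks, seed = 1))
    css <- suppressWarnings(
      select_n_signatures(unname(disc$signatures), nm, cl))
    list(ds = ds, nm = nm, clinical = cl, disc = disc, css = css)
  })
}

## small planted netMatrix: `k_signal` genes track the outcome states
planted_netmatrix <- function(n_genes = 60, n_samples = 80, k_signal = 10,
                              shift = 3, seed = 5) {
  withr_seed(seed)
  state <- rep(c(1L, 0L), each = n_samples / 2)
  nm <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
               dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                               sprintf("s%03d", seq_len(n_samples))))
  nm[seq_len(k_signal), state == 1L] <- nm[seq_len(k_signal), state == 1L] + shift
  clinical <- data.frame(
    sample_id = colnames(nm),
    dfs_time = ifelse(state == 1L, rexp(n_samples, 1 / 25), rexp(n_samples, 1 / 200)),
    dfs_event = ifelse(state == 1L, rbinom(n_samples, 1, 0.8),
                       rbinom(n_samples, 1, 0.1)))
  list(nm = nm, clinical = clinical, state = state,
       signal_genes = rownames(nm)[seq_len(k_signal)])
}
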