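# Shared fixtures built in code at test time.

# the ten-echo synthesis schedule, eta = k/11 for k = 2..11
synth_sched <- echo_schedule()

# the eleven-echo physical acquisition schedule (13.2 .. 145.2 ms)
invivo_sched <- echo_schedule(te_ms = seq(13.2, 145.2, by = 13.2))

# a small noiseless series with smoothly varying ground truth
make_clean_series <- function(n = 8, sched = synth_sched) {
  s0 <- matrix(seq(0.2, 1, length.out = n * n), n, n)
  tt <- matrix(seq(0.1, 3.5, length.out = n * n), n, n)
  list(series = image_series(decay_signal(s0, tt, sched), sched),
       s0 = s0, t = tt)
}

# random ground-truth maps spanning the training ranges (away from the
# exact endpoints so relative-error checks are well-defined)
random_truth_maps <- function(n, seed) {
  with_seed_test(seed, list(
    s0 = matrix(runif(n * n, 0.05, 1), n, n),
    t = matrix(runif(n * n, 0.05, 3.95), n, n)))
}

withr_tempdir <- function() {
  d <- tempfile("t2relax-test-")
  dir.create(d)
  d
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
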