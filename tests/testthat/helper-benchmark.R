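# Memoized heavy benchmark runs shared by the acceptance tests.  Conditions:
# 5 classes, 8 bands, 128 x 128 scenes, 500 source training patches per
# class, 3 seeds, epochs 10/30/24 (1:10 of the full protocol).
bench_env <- new.env()

bench_config <- function() {
  train_config(source_epochs = 10L, adversarial_epochs = 30L,
               ccsa_epochs = 24L)
}

bench_strong <- function() {
  if (is.null(bench_env$strong)) {
    bench_env$strong <- run_shift_benchmark(
      "strong", seeds = 1:3, shots = c(1L, 5L),
      methods = c("source-only", "adda", "ccsa", "proposed"),
      config = bench_config())
  }
  bench_env$strong
}

bench_none <- function() {
  if (is.null(bench_env$none)) {
    bench_env$none <- run_shift_benchmark(
      "none", seeds = 1:3, shots = 5L,
      methods = c("source-only", "proposed"),
      config = bench_config())
  }
  bench_env$none
}

bench_cv <- function() {
  if (is.null(bench_env$cv)) {
    bd <- benchmark_data(benchmark_suite(1L)$strong)
    bench_env$cv <- kfold_cv(bd$source_train, k = 3L, config = bench_config())
  }
  bench_env$cv
}

bench_mean <- function(d, method, shot = NULL) {
  rows <- d$method == method &
    if (is.null(shot)) is.na(d$shots) else !is.na(d$shots) & d$shots == shot
  mean(d$accuracy[rows])
}
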