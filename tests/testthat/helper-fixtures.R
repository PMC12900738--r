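# Packaged reference tables (transcribed published tables; masked cells NA)

fixture_path <- function(f) system.file("extdata", f, package = "padpref")

read_fixture <- function(f) {
  utils::read.csv(fixture_path(f), stringsAsFactors = FALSE,
                  check.names = FALSE)
}

norm_labels <- function() pad_norms()$label

# rows of a PAD table with all three components printed
complete_pad_rows <- function(df) df[stats::complete.cases(df[c("P", "A", "D")]), ]

# small deterministic epoch_set built from an explicit array
make_epochs <- function(data, fs = 500, t0 = -200,
                        channels = c("Fp1", "Fp2", "Cz", "M1", "M2"),
                        condition = "like") {
  epoch_set(data, fs = fs, t0 = t0, channels = channels,
            condition = condition)
}

# steady-state amplitude of a filtered sinusoid, measured over the central
# third of a long signal (away from zero-phase edge padding)
sine_gain <- function(freq, filter_fun, fs = 500, n = 4000) {
  x <- sin(2 * pi * freq * (0:(n - 1)) / fs)
  ep <- epoch_set(array(x, c(1, 1, n)), fs, -200, "Cz", "like")
  y <- filter_fun(ep)$data[1, 1, ]
  mid <- seq(round(n / 3), round(2 * n / 3))
  max(abs(y[mid]))
}
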