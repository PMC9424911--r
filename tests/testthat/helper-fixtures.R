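# Shared fixtures, built lazily and cached for the whole test run.
# Heavy objects (synthetic sessions, the trained decoder) are expensive, so
# every test file pulls them from here instead of regenerating.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

default_cfg <- function() fixture("cfg", function() synth_config(seed = 11))

# one slight session: 2 trials per class, the shared training corpus
slight_session <- function() fixture("slight_session", function() {
  generate_session(sfe_classes(), 2, default_cfg(), seed = 101)
})

regular_session <- function() fixture("regular_session", function() {
  generate_session(sfe_classes(), 1, default_cfg(), intensity = "regular",
                   seed = 102)
})

slight_low <- function() fixture("slight_low", function() {
  bandpass(slight_session(), decoding_band())
})

slight_high <- function() fixture("slight_high", function() {
  bandpass(slight_session(), screening_band())
})

regular_high <- function() fixture("regular_high", function() {
  bandpass(regular_session(), screening_band())
})

# the fully trained decoder at the study conditions: 400 windows/class,
# 30 epochs (trained once, reused by decoder and engine tests)
trained_models <- function() fixture("models", function() {
  train_decoder(slight_session(), regular_session(), n_per_class = 400,
                n_on = 400, epochs = 30, seed = 7)
})

# small windows for unit-level operations
tiny_window <- function(seed = 1, ch = 30, n = 100, sd = 5) {
  set.seed(seed)
  m <- matrix(rnorm(ch * n, sd = sd), ch, n)
  rownames(m) <- if (ch == 30) sfe_montage() else paste0("ch", seq_len(ch))
  m
}

sine_recording <- function(freq, rate = 1000, dur = 2, ch = 1, amp = 10) {
  t <- seq_len(rate * dur) / rate
  data <- matrix(rep(amp * sin(2 * pi * freq * t), each = ch), ch,
                 byrow = FALSE)
  eeg_recording(data, rate, paste0("ch", seq_len(ch)))
}
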