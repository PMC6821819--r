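# small constructors used across the suite

make_events <- function(donor, receiver, start_min = seq_along(donor),
                        duration_min = 1L, x_mm = 1, y_mm = 1) {
  data.frame(donor = donor, receiver = receiver,
             start_min = as.integer(start_min),
             duration_min = as.integer(rep_len(duration_min, length(donor))),
             x_mm = rep_len(x_mm, length(donor)),
             y_mm = rep_len(y_mm, length(donor)),
             stringsAsFactors = FALSE)
}

make_castes <- function(ants, foragers = character(0)) {
  data.frame(ant = ants,
             caste = ifelse(ants %in% foragers, "F", "NF"),
             stringsAsFactors = FALSE)
}

make_scans <- function(minute, donor, receiver, x_mm = 1, y_mm = 1) {
  data.frame(minute = as.integer(minute), donor = donor, receiver = receiver,
             x_mm = rep_len(x_mm, length(minute)),
             y_mm = rep_len(y_mm, length(minute)),
             stringsAsFactors = FALSE)
}

no_visits <- function() {
  data.frame(ant = character(), start_s = numeric(), duration_s = numeric(),
             stringsAsFactors = FALSE)
}
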