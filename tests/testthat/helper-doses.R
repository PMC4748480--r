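# shared helpers for the test suite

seven <- c("dn_min", "dn_max", "df_min", "df_max", "di_min", "di_max", "unit")

# exact attribute-wise comparison with sentinel semantics
expect_same_doses <- function(got, want) {
  for (a in seven)
    expect_true(all(rxsig:::value_equal(got[[a]], want[[a]])),
                label = sprintf("attribute %s (got %s, want %s)", a,
                                paste(got[[a]], collapse = "/"),
                                paste(want[[a]], collapse = "/")))
}

expect_tuple <- function(text, dn_min, dn_max, df_min, df_max,
                         di_min, di_max, unit, ...) {
  got <- parse_dose(text, ...)
  want <- structured_dose(dn_min, dn_max, df_min, df_max, di_min, di_max, unit)
  expect_same_doses(got, want)
}
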