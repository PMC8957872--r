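# Shared fixtures: everything is generated in code, no stored data.

uq2_topology <- local({
  top <- NULL
  function() {
    if (is.null(top)) top <<- build_topology("UQ", 2)
    top
  }
})

all_group_pairs <- function(top = uq2_topology()) {
  t(combn(names(top$proton_groups), 2))
}

# minimal three-peak table (reference + one strong + one weak)
tiny_peak_table <- function() {
  data.frame(group_a = c("H_W", "H_W", "H_W"),
             group_b = c("H_MN", "H_X", "H_Y"),
             volume = c(2.4e5, 4.8e5, 0.6e5),
             spectrum = "NOESY", environment = "d6-DMSO",
             overlap_flag = FALSE, stringsAsFactors = FALSE)
}

# linear-in-knots isotherm curve built from an exact function of pressure
linear_isotherm <- function(a = 100, b = 1.5, pmax = 40, n = 200,
                            x = 1, ...) {
  p <- seq(0, pmax, length.out = n)
  isotherm_curve(area = a - b * p, pressure = p, x = x, ...)
}
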