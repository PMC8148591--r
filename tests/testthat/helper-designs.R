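# Shared fixtures: standardized single-substance curves and the study's
# equitoxic mixture designs, built in code from the reference parameter set.

t1_curves <- table1_curves("modeling")

mix_a_hyper <- equitoxic_design(
  t1_curves[c("chlorpyrifos", "chlorpyrifos-oxon")],
  label = "Hyperactive Mixture A")
mix_a_hypo <- equitoxic_design(
  t1_curves[c("carbamazepine", "propafenone")],
  label = "Hypoactive Mixture A")
mix_b_hyper <- equitoxic_design(
  t1_curves[c("hexaconazole", "chlorpyrifos")],
  label = "Hyperactive Mixture B")
mix_b_hypo <- equitoxic_design(
  t1_curves[c("abamectin", "propafenone")],
  label = "Hypoactive Mixture B")
mix_c <- equitoxic_design(
  t1_curves[c("chlorpyrifos", "hexaconazole", "chlorpyrifos-oxon")],
  label = "Mixture C")

design_fractions <- function(design) {
  vapply(design$components, `[[`, numeric(1), "fraction")
}
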