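# Small builders shared across test files.

ibu_skin_model <- function() {
  # mirrors the free-acid / human-skin row of the reference panel
  membrane_model_from_kinetics(kp = 0.74e-3, lt = 1.17, h = 0.05)
}

default_cell <- function() cell_config(area = 1, V_receptor = 8,
                                       V_sample = 0.5, C_donor = 50000)

random_model <- function() {
  membrane_model_from_kinetics(kp = runif(1, 0.4e-3, 4.2e-3),
                               lt = runif(1, 0.5, 2.2),
                               h = sample(c(0.03, 0.05), 1))
}

tiny_registry <- function() {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "acronym,name,M_pair,M_active,chain_length,branched",
    "[IBU],free acid,206.284,206.284,0,FALSE",
    "[ValOEt][IBU],ethyl ester pair,351.485,206.284,2,FALSE"), path)
  read_compound_registry(path)
}
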