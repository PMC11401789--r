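# Regenerates the configuration resources under inst/extdata from the
# package's own builders. Run from the package root after editing the
# builders:
#   Rscript data-raw/make_resources.R
pkgload::load_all(".", quiet = TRUE)

write.csv(default_age_classes(), "inst/extdata/age_classes.csv",
          row.names = FALSE)
write.csv(build_wear_age_lookup(), "inst/extdata/wear_age_lookup.csv",
          row.names = FALSE)
write.csv(mass_equations(), "inst/extdata/mass_equations.csv",
          row.names = FALSE)
cat("resources written\n")
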