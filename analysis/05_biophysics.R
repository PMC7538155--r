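#!/usr/bin/env Rscript
# Physical interpretation of the fitted diffusion constant: thermal
# reference, membrane-tube confinement, stochastic force strength and the
# implied active forces.

library(iknm)

dir.create("results", showWarnings = FALSE)

report <- biophysics_report(D = 0.09, R = 3.5)
jsonlite::write_json(report, "results/biophysics.json", auto_unbox = TRUE,
                     digits = NA)

message(sprintf(
  "free thermal diffusivity %.1f um^2/min is ~%.0f times the fitted D: nuclei are far less mobile than thermal spheres in water",
  report$D_thermal_um2_min, report$thermal_ratio
))
message(sprintf(
  "membrane-tube confinement suppresses diffusion by %.1e: thermal motion inside the cell tube is ~1e3-1e4 times too slow",
  report$D_tube_over_D_thermal
))
message(sprintf(
  "matching the fitted D requires stochastic forces of %.1f-%.0f nN over 10 ms-1 s correlation times: the scale of collective cytoskeletal transport",
  report$force_range_nN[1], report$force_range_nN[2]
))
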