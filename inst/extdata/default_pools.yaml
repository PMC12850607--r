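# Synthetic default pool table for the digital kidney CEST phantom.
#
# Amplitudes and widths are phenomenological stand-ins chosen to give the
# compartments a clearly detectable, qualitatively realistic contrast
# pattern (cortex: glucose-like effect at +1.0 ppm; medulla:
# creatinine-like effect at +2.0 ppm; pelvis: urea-like effect at +1.0 ppm
# with a dominant NOE-like upfield pool at -3.5 ppm). They are NOT derived
# from metabolite concentrations or exchange rates. Users may substitute
# their own table with the same schema.
schema_version: 1
compartments:
  background:
    s0: 0.05
    fat_fraction: 0.0
    pools:
      - {offset_ppm: 0.0, amplitude: 0.0, width_ppm: 1.6}
  surround:
    s0: 1.0
    fat_fraction: 0.0
    pools:
      - {offset_ppm: 0.0, amplitude: 0.80, width_ppm: 1.6}
  cortex:
    s0: 1.0
    fat_fraction: 0.0
    pools:
      - {offset_ppm: 0.0, amplitude: 0.80, width_ppm: 1.6}
      - {offset_ppm: 1.0, amplitude: 0.06, width_ppm: 1.2}
  medulla:
    s0: 1.0
    fat_fraction: 0.0
    pools:
      - {offset_ppm: 0.0, amplitude: 0.80, width_ppm: 1.6}
      - {offset_ppm: 2.0, amplitude: 0.08, width_ppm: 1.2}
  pelvis:
    s0: 1.0
    fat_fraction: 0.0
    pools:
      - {offset_ppm: 0.0, amplitude: 0.80, width_ppm: 1.6}
      - {offset_ppm: 1.0, amplitude: 0.05, width_ppm: 1.5}
      - {offset_ppm: -3.5, amplitude: 0.07, width_ppm: 2.0}
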