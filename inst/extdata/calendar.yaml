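# Example closure calendar: five survey cruises per year; the dominant
# stock closed March-May in the northern region, winter closures in the
# southern region.
survey_months: [3, 5, 7, 9, 11]
closures:
  - {region: MD, species: striped_bass, start: "03-01", end: "05-31"}
  - {region: VA, species: atlantic_croaker, start: "01-01", end: "01-15"}
  - {region: VA, species: spot, start: "12-08", end: "04-15"}
  - {region: VA, species: striped_bass, start: "01-01", end: "01-16"}
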