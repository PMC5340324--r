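{
  "sites": [
    ["0", "1"],
    ["0", "1"]
  ],
  "wildtype": "00",
  "data": [
    {
      "genotype": "00",
      "phenotype": 0,
      "stdev": 0,
      "n": 1
    },
    {
      "genotype": "01",
      "phenotype": 2,
      "stdev": 0,
      "n": 1
    },
    {
      "genotype": "10",
      "phenotype": 1,
      "stdev": 0,
      "n": 1
    },
    {
      "genotype": "11",
      "phenotype": 2,
      "stdev": 0,
      "n": 1
    }
  ]
}
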