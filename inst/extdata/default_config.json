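{
  "seed": 42,
  "nShared": 20,
  "nElapidMarkers": 5,
  "nViperidMarkers": 5,
  "effectSize": 1.0,
  "nContaminants": 2,
  "rtJitterSd": 0.1,
  "mzErrorSd": 0.002,
  "log10IntensitySd": 0.2,
  "dropoutProb": 0.02,
  "nBlanks": 2,
  "mzTol": 0.01,
  "rtTol": 0.5,
  "blankRatio": 3,
  "nIterations": 1000,
  "nExtractPerClass": 4,
  "classifier": "svm",
  "annotationMzTol": 0.05
}
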