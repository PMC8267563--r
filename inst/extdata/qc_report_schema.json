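{
  "title": "dtcqc single-file QC report",
  "required": {
    "file": "string",
    "source": "string",
    "build": "string",
    "data_kind": "string",
    "cluster": "string",
    "stages": "object",
    "passed": "boolean",
    "rejection_reason": "string or null",
    "rejection_stage": "string or null",
    "params": "object"
  },
  "stage": {
    "status": "pass | fail",
    "detail": "string or null",
    "counts": "object of numbers"
  }
}
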