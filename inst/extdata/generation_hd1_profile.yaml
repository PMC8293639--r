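# Per-procedure resource requirements for intrathecal administration of an
# HD disease-modifying therapy, following the GENERATION HD1 trial protocol.
# minutes are per person; persons is the number engaged simultaneously.
name: GENERATION HD1 intrathecal administration
admins_per_patient_per_year: 6.5  # every-8-week dosing: 52 / 8
steps:
  - name: patient preparation
    resource: proceduralist
    minutes: 15
    persons: 1
  - name: collection of CSF samples for analysis
    resource: proceduralist
    minutes: 40
    persons: 1
  - name: IT bolus injection
    resource: proceduralist
    minutes: 5
    persons: 1
  - name: patient check-in and education
    resource: nurse
    minutes: 10
    persons: 1
  - name: facility preparation
    resource: nurse
    minutes: 10
    persons: 1
  - name: patient preparation
    resource: nurse
    minutes: 15
    persons: 1
  - name: CSF collection
    resource: nurse
    minutes: 40
    persons: 2
  - name: IT bolus injection
    resource: nurse
    minutes: 5
    persons: 2
  - name: patient mobilisation and monitoring
    resource: nurse
    minutes: 30
    persons: 1
  - name: facility preparation
    resource: facility
    minutes: 10
    persons: 1
  - name: patient preparation
    resource: facility
    minutes: 15
    persons: 1
  - name: CSF collection
    resource: facility
    minutes: 40
    persons: 1
  - name: IT bolus injection
    resource: facility
    minutes: 5
    persons: 1
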