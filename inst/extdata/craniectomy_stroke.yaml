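# Phenotype rule set: decompressive craniectomy for space-occupying
# supratentorial infarction, from ICD-9-CM billing codes.
# A record is positive when an inclusion diagnosis AND an inclusion
# procedure match and no exclusion code (either axis) is present.
name: craniectomy_stroke
inclusion:
  diagnosis:
    - '433.11'   # occlusion & stenosis of carotid artery, with infarction
    - '434.01'   # cerebral thrombosis, with infarction
    - '434.11'   # cerebral embolism, with infarction
    - '434.91'   # cerebral artery occlusion, unspecified, with infarction
  procedure:
    - '01.24'    # craniotomy
    - '01.25'    # craniectomy
    - '01.39'    # other incision of brain
    - '01.53'    # lobectomy of brain
    - '01.59'    # other excision of lesion or tissue of brain
exclusion:
  diagnosis:
    - '191.x'    # malignant neoplasm of the brain
    - '198.3'    # secondary malignant neoplasm of brain and spinal cord
    - '324.0'    # intracranial abscess
    - '430'      # subarachnoid hemorrhage
    - '433.01'   # occlusion & stenosis of basilar artery, with infarction
    - '433.21'   # occlusion & stenosis of vertebral artery, with infarction
    - '437.3'    # cerebral aneurysm, unruptured
    - '437.5'    # Moyamoya disease
    - '437.6'    # intracranial venous sinus thrombosis
    - '443.24'   # dissection of the vertebral artery
    - '747.81'   # congenital anomalies of the cerebrovascular system
    - '800.xx'   # fracture of the vault of the skull
    - '801.xx'   # fracture of the base of the skull
    - '851.xx'   # traumatic cerebral contusion
    - '852.xx'   # traumatic subarachnoid, subdural, or extradural hemorrhage
    - '853.xx'   # other and unspecified intracranial hemorrhage after injury
    - '854.xx'   # intracranial injury of other and unspecified nature
  procedure:
    - '03.09'    # laminectomy (C1 laminectomy accompanies suboccipital decompression)
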