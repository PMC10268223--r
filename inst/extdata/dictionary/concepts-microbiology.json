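{"samp":{"class":"lgl_cncpt","description":"culture specimen sampled","category":"microbiology","target":"ts_tbl","aggregate":"any","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50374],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50375],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50376],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50377],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50378],"class":"sel_itm"}],"eav_absolute":[{"table":"microbiologyevents","class":"col_itm","callback":"flag_true"}],"wide_relative":[{"table":"microlab","class":"col_itm","callback":"flag_true"}],"eav_relative":[{"table":"culture","class":"col_itm","callback":"flag_true"}]}}}
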