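{"age":{"class":"num_cncpt","description":"patient age","category":"demographics","unit":["years"],"min":0,"max":130,"omopid":4265453,"target":"id_tbl","aggregate":"first","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50379],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50380],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50381],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50382],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50383],"class":"sel_itm"}],"eav_absolute":[{"table":"patients","class":"col_itm","value_column":"age"}],"wide_relative":[{"table":"unitstays","class":"col_itm","value_column":"age"}],"eav_relative":[{"table":"admissions","class":"col_itm","value_column":"age"}]}},"sex":{"class":"fct_cncpt","description":"patient sex","category":"demographics","levels":["Male","Female"],"omopid":37116947,"target":"id_tbl","aggregate":"first","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50384],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50385],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50386],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50387],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50388],"class":"sel_itm"}],"eav_absolute":[{"table":"patients","class":"col_itm","value_column":"sex"}],"wide_relative":[{"table":"unitstays","class":"col_itm","value_column":"sex"}],"eav_relative":[{"table":"admissions","class":"col_itm","value_column":"sex"}]}},"height":{"class":"num_cncpt","description":"patient height","category":"demographics","unit":["cm"],"min":0,"max":260,"target":"id_tbl","aggregate":"first","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50389],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50390],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50391],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50392],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90085],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90085"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90085],"class":"sel_itm"}]}},"weight":{"class":"num_cncpt","description":"patient weight","category":"demographics","unit":["kg"],"min":0,"max":500,"target":"id_tbl","aggregate":"first","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50393],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50394],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50395],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50396],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50397],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90086],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90086"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90086],"class":"sel_itm"}]}},"diab":{"class":"lgl_cncpt","description":"diabetes status (ICD-9 250.xx)","category":"demographics","target":"id_tbl","aggregate":"any","sources":{"mimic":[{"table":"diagnoses_icd","class":"col_itm","callback":"transform_fun(grep_diab)"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50399],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50400],"class":"sel_itm"}],"miiv":[{"table":"diagnoses_icd","class":"col_itm","callback":"transform_fun(grep_diab)"}],"eav_absolute":[{"table":"diagnoses_icd","class":"col_itm","callback":"transform_fun(grep_diab)"}],"wide_relative":[{"table":"diagnosis","class":"col_itm","callback":"transform_fun(grep_diab)"}],"eav_relative":[{"table":"diagnosis","class":"col_itm","callback":"transform_fun(grep_diab)"}]}},"bmi":{"class":"rec_cncpt","description":"body mass index","category":"demographics","concepts":["height","weight"],"callback":"bmi_cb","target":"id_tbl"}}
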