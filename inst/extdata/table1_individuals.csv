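individual_id,sex,age_class,ritual,strontium,dental,funerary
MV 1,male,middle_adult,inhumation,TRUE,TRUE,TRUE
MV 2,female,middle_adult,inhumation,TRUE,TRUE,TRUE
MV 3,male,young_adult,inhumation,TRUE,TRUE,TRUE
MV 4,female,old_adult,inhumation,FALSE,FALSE,TRUE
MV 5,male,old_adult,inhumation,TRUE,TRUE,TRUE
MV 6,unknown,unknown,cremation,FALSE,FALSE,TRUE
MV 7,probable_female,old_adult,inhumation,TRUE,TRUE,TRUE
MV 8,male,middle_adult,inhumation,TRUE,TRUE,TRUE
MV 9,female,old_adult,inhumation,FALSE,FALSE,TRUE
MV 10,unknown,child,inhumation,TRUE,FALSE,TRUE
MV 12,male,young_adult,inhumation,TRUE,TRUE,TRUE
MV 13,unknown,infant,inhumation,FALSE,FALSE,TRUE
MV 14,female,old_adult,inhumation,FALSE,FALSE,TRUE
MV 15,male,middle_adult,inhumation,TRUE,TRUE,TRUE
MV 16,unknown,unknown,cremation,FALSE,FALSE,TRUE
MV 17,unknown,infant,inhumation,FALSE,FALSE,TRUE
MV 18,unknown,child,inhumation,FALSE,FALSE,TRUE
MV 19,male,young_adult,inhumation,TRUE,TRUE,TRUE
MV 20,female,old_adult,inhumation,TRUE,TRUE,TRUE
MV 21,female,middle_adult,inhumation,TRUE,TRUE,TRUE
MV 22,male,adolescent,inhumation,TRUE,TRUE,TRUE
MV 23,unknown,infant,inhumation,FALSE,FALSE,TRUE
MV 24,unknown,child,inhumation,TRUE,FALSE,TRUE
MV 25,unknown,child,inhumation,TRUE,FALSE,TRUE
MV 26,male,young_adult,inhumation,TRUE,TRUE,TRUE
MV 27,male,young_adult,inhumation,TRUE,TRUE,TRUE
MV 28,unknown,unknown,cremation,FALSE,FALSE,TRUE
MV 29,unknown,child,inhumation,FALSE,FALSE,TRUE
MV 30,male,adolescent,inhumation,TRUE,TRUE,TRUE
MV 31,female,old_adult,inhumation,TRUE,FALSE,TRUE
MV 32,unknown,unknown,cremation,FALSE,FALSE,TRUE
MV 33,unknown,child,inhumation,FALSE,FALSE,TRUE
MV 35,unknown,child,inhumation,TRUE,FALSE,TRUE
MV 36,male,middle_adult,inhumation,FALSE,TRUE,TRUE
MV 37,unknown,child,inhumation,FALSE,FALSE,TRUE
MV 39,male,young_adult,inhumation,TRUE,TRUE,TRUE
MV A,female,young_adult,inhumation,TRUE,TRUE,FALSE
MV B,male,young_adult,inhumation,TRUE,TRUE,FALSE
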