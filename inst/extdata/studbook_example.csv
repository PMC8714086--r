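id,sire,dam,sex,birth_date,location,is_reference
F001,0,0,male,1970-10-08,LOC01,FALSE
F002,0,0,female,1971-05-23,LOC01,FALSE
F003,0,0,male,1972-10-28,LOC01,FALSE
F004,0,0,female,1972-12-08,LOC01,FALSE
F005,0,0,male,1970-05-10,LOC02,FALSE
F006,0,0,female,1971-06-06,LOC02,FALSE
F007,0,0,male,1971-09-07,LOC02,FALSE
F008,0,0,female,1972-09-18,LOC01,FALSE
F009,0,0,male,1970-06-02,LOC03,FALSE
F010,0,0,female,1972-12-20,LOC03,FALSE
G1-001,0,F002,female,1979-01-11,LOC01,FALSE
G1-002,0,0,female,1979-08-27,LOC03,FALSE
G1-003,F007,0,female,1980-10-09,LOC03,FALSE
G1-004,F003,F002,male,1977-10-20,LOC01,FALSE
G1-005,0,0,male,1979-06-13,LOC01,FALSE
G1-006,F005,0,male,1973-08-20,LOC03,FALSE
G1-007,0,F006,female,1977-05-12,LOC02,FALSE
G1-008,0,0,male,1977-02-01,LOC01,FALSE
G1-009,0,0,female,1974-10-28,LOC01,FALSE
G1-010,F005,0,female,1979-07-24,LOC03,FALSE
G1-011,F003,0,male,1979-12-26,LOC03,FALSE
G1-012,0,0,male,1978-07-27,LOC03,FALSE
G1-013,0,0,female,1981-05-14,LOC03,FALSE
G2-001,G1-011,G1-001,female,1987-08-24,LOC01,TRUE
G2-002,G1-008,G1-002,female,1983-12-09,LOC02,TRUE
G2-003,G1-004,G1-002,female,1983-05-28,LOC03,FALSE
G2-004,G1-008,G1-003,female,1991-01-20,LOC03,TRUE
G2-005,G1-005,G1-003,male,1987-12-01,LOC03,TRUE
G2-006,0,0,female,1987-06-30,LOC03,TRUE
G2-007,G1-006,G1-003,female,1986-12-21,LOC03,TRUE
G2-008,G1-011,G1-003,male,1984-04-14,LOC03,FALSE
G2-009,G1-011,0,male,1988-01-06,LOC02,FALSE
G2-010,G1-012,G1-007,male,1984-07-10,LOC02,TRUE
G2-011,0,G1-007,female,1983-05-29,LOC02,TRUE
G2-012,G1-012,0,female,1987-05-27,LOC02,TRUE
G2-013,0,G1-007,female,1985-12-01,LOC02,TRUE
G2-014,0,0,male,1989-12-19,LOC01,TRUE
G2-015,G1-004,G1-009,female,1983-02-10,LOC01,FALSE
G2-016,G1-008,G1-009,male,1985-03-19,LOC01,TRUE
G2-017,0,G1-010,male,1989-07-16,LOC03,FALSE
G2-018,G1-004,0,female,1983-04-14,LOC01,TRUE
G2-019,G1-011,0,male,1984-05-01,LOC03,TRUE
G2-020,G1-012,G1-013,female,1985-01-13,LOC03,TRUE
G2-021,0,G1-013,male,1984-03-20,LOC03,TRUE
G3-001,G2-016,G2-001,male,1997-11-05,LOC01,FALSE
G3-002,G2-010,G2-001,female,1991-08-25,LOC02,TRUE
G3-003,G2-005,G2-001,male,1993-02-26,LOC01,TRUE
G3-004,G2-010,G2-001,male,1999-03-31,LOC01,TRUE
G3-005,G2-010,G2-002,male,1987-09-20,LOC02,TRUE
G3-006,G2-010,G2-002,male,1994-09-21,LOC02,TRUE
G3-007,G2-005,G2-003,male,1995-05-27,LOC03,TRUE
G3-008,G2-021,G2-004,male,2003-06-13,LOC03,TRUE
G3-009,G2-005,G2-004,female,1996-11-17,LOC03,TRUE
G3-010,G2-005,G2-006,female,1992-12-16,LOC03,TRUE
G3-011,G2-010,G2-006,male,1997-10-12,LOC03,TRUE
G3-012,G2-005,G2-006,male,1996-12-03,LOC03,TRUE
G3-013,G2-005,G2-006,male,1996-02-10,LOC03,TRUE
G3-014,G2-005,G2-006,male,1989-12-01,LOC03,FALSE
G3-015,G2-008,G2-007,female,1992-10-31,LOC03,TRUE
G3-016,G2-019,G2-011,female,1990-09-17,LOC02,FALSE
G3-017,G2-009,G2-011,male,1993-04-29,LOC02,FALSE
G3-018,G2-014,G2-011,male,1995-02-05,LOC02,TRUE
G3-019,G2-005,G2-011,male,1991-01-29,LOC02,TRUE
G3-020,G2-009,G2-012,male,1993-08-14,LOC03,TRUE
G3-021,G2-014,G2-013,male,1992-02-14,LOC02,TRUE
G3-022,G2-019,G2-018,male,1990-01-10,LOC01,TRUE
G3-023,G2-016,G2-020,female,1995-01-25,LOC01,TRUE
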